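test_that("parsimony change counts match hand-worked cases", {
  # presence only in two sister tips: one gain (leupyrrin-like pattern)
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  expect_equal(parsimony_changes(tree, c(A = 1, B = 1, C = 0, D = 0)), 1L)
  expect_equal(parsimony_changes(tree, c(A = 0, B = 0, C = 0, D = 0)), 0L)
  bal <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(parsimony_changes(bal, c(A = 1, B = 0, C = 1, D = 0)), 2L)
})

test_that("Sankoff counts equal Fitch parsimony on random binary trees", {
  skip_if_not_installed("phangorn")
  for (seed in 1:8) {
    tree <- oracle_random_tree(10, seed)
    set.seed(seed + 50)
    v <- setNames(sample(0:1, 10, replace = TRUE), tree$tip.label)
    dat <- phangorn::phyDat(matrix(as.character(v), ncol = 1,
                                   dimnames = list(names(v), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(parsimony_changes(tree, v),
                 as.integer(phangorn::parsimony(tree, dat)))
  }
})

test_that("chi-square screen reproduces hand-computed 2x2 arithmetic", {
  # table [[30,5],[5,32]]: sum O-E deviations give 37.533 uncorrected,
  # 34.699 with the continuity correction (hand formula n(|ad-bc|-n/2)^2 /
  # (r1 r2 c1 c2))
  g <- c(rep(1L, 35), rep(0L, 37))
  m <- c(rep(1L, 30), rep(0L, 5), rep(1L, 5), rep(0L, 32))
  strains <- sprintf("s%02d", 1:72)
  gm <- trait_matrix(matrix(g, 72, 1, dimnames = list(strains, "G1")), "GCF")
  mm <- trait_matrix(matrix(m, 72, 1, dimnames = list(strains, "M1")), "MF")
  res_y <- chisq_screen(gm, mm, correct = TRUE)
  res_u <- chisq_screen(gm, mm, correct = FALSE)
  expect_equal(res_u$statistic, 37.53325, tolerance = 1e-5)
  expect_equal(res_y$statistic, 34.69863, tolerance = 1e-5)
  expect_lt(res_y$statistic, res_u$statistic)
  expect_equal(res_y$verdict, "linked")
  # agreement with the conventional implementation
  expect_equal(res_y$statistic,
               unname(chisq.test(table(g, m))$statistic), tolerance = 1e-8)
  expect_equal(res_y$p, chisq.test(table(g, m))$p.value, tolerance = 1e-8)
})

test_that("proportional and anti-associated tables are not linked", {
  strains <- sprintf("s%02d", 1:40)
  # independent: identical presence probability rows -> statistic 0
  g <- rep(c(1L, 0L), each = 20)
  m <- rep(c(1L, 0L, 1L, 0L), each = 10)
  gm <- trait_matrix(matrix(g, 40, 1, dimnames = list(strains, "G1")), "GCF")
  mm <- trait_matrix(matrix(m, 40, 1, dimnames = list(strains, "M1")), "MF")
  res <- chisq_screen(gm, mm, correct = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$verdict, "not-linked")

  # perfect anti-association: significant but direction filter rejects
  m2 <- 1L - g
  mm2 <- trait_matrix(matrix(m2, 40, 1, dimnames = list(strains, "M1")), "MF")
  res <- chisq_screen(gm, mm2)
  expect_lt(res$p, 0.01)
  expect_equal(res$verdict, "not-linked")
  res_nf <- chisq_screen(gm, mm2, direction_filter = FALSE)
  expect_equal(res_nf$verdict, "linked")
})

test_that("degenerate (constant) traits are flagged, never linked", {
  strains <- sprintf("s%02d", 1:10)
  gm <- trait_matrix(matrix(1L, 10, 1, dimnames = list(strains, "G1")), "GCF")
  mm <- trait_matrix(matrix(rep(c(0L, 1L), 5), 10, 1,
                            dimnames = list(strains, "M1")), "MF")
  res <- chisq_screen(gm, mm)
  expect_true(res$degenerate)
  expect_equal(res$verdict, "not-linked")
})

test_that("chi-square screen is invariant to strain ordering", {
  set.seed(12)
  strains <- sprintf("s%02d", 1:30)
  g <- matrix(rbinom(60, 1, 0.4), 30, 2, dimnames = list(strains, c("G1", "G2")))
  m <- matrix(rbinom(60, 1, 0.4), 30, 2, dimnames = list(strains, c("M1", "M2")))
  r1 <- chisq_screen(trait_matrix(g, "GCF"), trait_matrix(m, "MF"))
  perm <- sample(30)
  r2 <- chisq_screen(trait_matrix(g[perm, ], "GCF"),
                     trait_matrix(m[rev(perm), ], "MF"))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$verdict, r2$verdict)
})

test_that("eligibility rules out single-clade traits regardless of overlap", {
  tree <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  strains <- tree$tip.label
  # GCF with 2 scattered gains; MF confined to one cherry (1 gain)
  g <- matrix(c(1L, 0L, 1L, 0L, 1L, 0L), 6, 1,
              dimnames = list(strains, "G1"))
  m <- matrix(c(1L, 1L, 0L, 0L, 0L, 0L), 6, 1,
              dimnames = list(strains, "M1"))
  res <- associate_all(trait_matrix(g, "GCF"), trait_matrix(m, "MF"), tree,
                       seed = 1, n_restarts = 2)
  expect_equal(res$verdict, "ineligible")
  expect_false(res$eligible)
  expect_equal(res$changes_mf, 1L)
  expect_true(is.na(res$p))
})

test_that("the pair model is symmetric under swapping the traits' roles", {
  tree <- simulate_tree(24, seed = 31)
  ab <- simulate_trait(tree, coupled_pair_rates(0.6, 3, 0.6, 3, 8),
                       root = 1, seed = 77)
  a <- setNames(ab[, 1], rownames(ab)); b <- setNames(ab[, 2], rownames(ab))
  # exact symmetry at the likelihood level: swapping the traits while
  # relabeling (alpha <-> beta, gamma <-> delta) leaves lnL unchanged
  r <- exp(runif(8, log(0.1), log(5)))
  Q_ab <- rate_matrix4(r[1], r[2], r[3], r[4], r[5], r[6], r[7], r[8])
  Q_ba <- rate_matrix4(r[3], r[4], r[1], r[2], r[7], r[8], r[5], r[6])
  expect_equal(tree_log_likelihood(tree, pair_states(a, b), Q_ab),
               tree_log_likelihood(tree, pair_states(b, a), Q_ba),
               tolerance = 1e-9)
  # at the fitted level the verdict agrees and D matches to optimizer
  # resolution
  am <- matrix(a, ncol = 1, dimnames = list(names(a), "G1"))
  bm <- matrix(b, ncol = 1, dimnames = list(names(b), "M1"))
  r1 <- associate_all(trait_matrix(am, "GCF"), trait_matrix(bm, "MF"), tree,
                      seed = 3, n_restarts = 4)
  r2 <- associate_all(trait_matrix(bm, "GCF"), trait_matrix(am, "MF"), tree,
                      seed = 3, n_restarts = 4)
  expect_identical(r1$eligible, r2$eligible)
  expect_equal(r1$D, r2$D, tolerance = 0.2)
  expect_identical(r1$verdict, r2$verdict)
})

test_that("BH adjustment never enlarges the linked set", {
  tree <- simulate_tree(24, seed = 31)
  set.seed(9)
  g <- matrix(rbinom(72, 1, 0.5), 24, 3,
              dimnames = list(tree$tip.label, c("G1", "G2", "G3")))
  m <- matrix(rbinom(48, 1, 0.5), 24, 2,
              dimnames = list(tree$tip.label, c("M1", "M2")))
  raw <- associate_all(trait_matrix(g, "GCF"), trait_matrix(m, "MF"), tree,
                       seed = 2, n_restarts = 2)
  adj <- associate_all(trait_matrix(g, "GCF"), trait_matrix(m, "MF"), tree,
                       seed = 2, n_restarts = 2, p_adjust = "BH")
  linked_raw <- raw$verdict == "linked"
  linked_adj <- adj$verdict == "linked"
  expect_true(all(!linked_adj | linked_raw))
  ok <- !is.na(raw$p)
  expect_true(all(adj$p[ok] >= raw$p[ok] - 1e-12))
})

test_that("associate_all is reproducible given a seed", {
  tree <- simulate_tree(16, seed = 8)
  set.seed(4)
  g <- matrix(rbinom(32, 1, 0.5), 16, 2,
              dimnames = list(tree$tip.label, c("G1", "G2")))
  m <- matrix(rbinom(16, 1, 0.5), 16, 1,
              dimnames = list(tree$tip.label, "M1"))
  r1 <- associate_all(trait_matrix(g, "GCF"), trait_matrix(m, "MF"), tree,
                      seed = 11, n_restarts = 3)
  r2 <- associate_all(trait_matrix(g, "GCF"), trait_matrix(m, "MF"), tree,
                      seed = 11, n_restarts = 3)
  expect_identical(r1, r2)
})

test_that("known-pair evaluation counts correct and false positive links", {
  results <- data.frame(
    gcf_id = c("G1", "G2", "G3"), mf_id = c("M1", "M1", "M2"),
    verdict = c("linked", "linked", "linked"), method = "phylo",
    stringsAsFactors = FALSE)
  cat_ <- known_pair_catalog(data.frame(compound = "cmpA", gcf_id = "G1",
                                        mf_id = "M1"))
  ev <- evaluate_known_pairs(results, cat_)
  expect_equal(ev$correct_total, 1L)
  expect_equal(ev$false_positive_total, 1L)  # (G2, M1); (G3, M2) ignored

  # empty predictions
  none <- results; none$verdict <- "not-linked"
  ev0 <- evaluate_known_pairs(none, cat_)
  expect_equal(ev0$correct_total, 0L)
  expect_equal(ev0$false_positive_total, 0L)

  expect_error(evaluate_known_pairs(results, known_pair_catalog(
    data.frame(compound = "x", gcf_id = "G9", mf_id = "M1"))), "G9")
})

test_that("fold reduction excludes compounds the focal screen skipped", {
  # compound B: focal made no prediction -> comparator's 14 FPs excluded
  mk <- function(per) structure(list(per_compound = per,
                                     correct_total = sum(per$correct),
                                     false_positive_total = sum(per$false_positives),
                                     method = "x"),
                                class = "evaluation_summary")
  focal <- mk(data.frame(compound = c("A", "B"), correct = c(TRUE, FALSE),
                         false_positives = c(3L, 0L),
                         predicted = c(TRUE, FALSE)))
  comp <- mk(data.frame(compound = c("A", "B"), correct = c(TRUE, TRUE),
                        false_positives = c(99L, 14L),
                        predicted = c(TRUE, TRUE)))
  expect_equal(fold_reduction(focal, comp), 33)
})

test_that("permutations preserve column sums; identity reproduces input", {
  set.seed(19)
  tree <- simulate_tree(12, seed = 2)
  g <- matrix(rbinom(24, 1, 0.5), 12, 2,
              dimnames = list(tree$tip.label, c("G1", "G2")))
  m <- matrix(rbinom(24, 1, 0.4), 12, 2,
              dimnames = list(tree$tip.label, c("M1", "M2")))
  gm <- trait_matrix(g, "GCF"); mm <- trait_matrix(m, "MF")
  cat_ <- known_pair_catalog(data.frame(compound = "c1", gcf_id = "G1",
                                        mf_id = "M1"))
  perms <- permutation_control(gm, mm, tree, cat_, n_perm = 3L, seed = 5,
                               methods = "chisq")
  for (pr in perms) {
    permuted <- unclass(mm)[pr$permutation, , drop = FALSE]
    expect_equal(colSums(permuted), colSums(unclass(mm)))
    expect_true(all(sort(pr$permutation) == seq_len(12)))
  }
  # an identity permutation reproduces the unpermuted summary
  base <- evaluate_known_pairs(chisq_screen(gm, mm), cat_)
  idm <- trait_matrix(unclass(mm)[seq_len(12), , drop = FALSE], "MF")
  expect_identical(evaluate_known_pairs(chisq_screen(gm, idm), cat_)$per_compound,
                   base$per_compound)
})
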