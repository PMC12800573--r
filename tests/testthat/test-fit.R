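test_that("median rate ratio over informative traits recovers the truth", {
  # single binary traits barely identify two rates, so per-trait estimates
  # scatter widely; the median over traits — the summary the analysis
  # reports — is the recoverable quantity. Light version here (72-tip
  # tree, ~30 informative traits at ratio 0.2); the paper-scale ratio
  # 0.016 sweep is in the acceptance suite.
  tree <- simulate_tree(72, seed = 2)
  Q <- rate_matrix2(0.4, 2)
  rs <- c()
  i <- 0L
  while (length(rs) < 30L && i < 120L) {
    i <- i + 1L
    v <- simulate_trait(tree, Q, root = "stationary", seed = 100 + i)
    if (length(unique(v)) < 2L) next
    f <- fit_model(tree, v, "single", seed = i, n_restarts = 3)
    if (f$converged) rs <- c(rs, f$rates[["q01"]] / f$rates[["q10"]])
  }
  expect_gte(length(rs), 30L)
  expect_gte(median(rs), 0.1)
  expect_lte(median(rs), 0.4)
})

test_that("constant traits are flagged degenerate", {
  tree <- simulate_tree(16, seed = 3)
  v <- setNames(rep(1L, 16), tree$tip.label)
  f <- fit_model(tree, v, "single", seed = 1)
  expect_true(f$degenerate)
  # no loss is observable: the loss rate is driven to the lower bound
  expect_lt(f$rates[["q10"]], 1e-4)
})

test_that("dependent fit never undercuts the independent fit", {
  for (i in 1:6) {
    tree <- simulate_tree(16, seed = 400 + i)
    Qp <- coupled_pair_rates(0.5, 1.5, 0.5, 1.5, sample(c(1, 4, 16), 1L))
    ab <- simulate_trait(tree, Qp, root = 1, seed = 500 + i)
    fi <- fit_model(tree, ab, "pair_independent", seed = i, n_restarts = 3)
    fd <- fit_model(tree, ab, "pair_dependent", seed = i + 60, n_restarts = 3)
    expect_gte(fd$lnL, fi$lnL - 1e-6)
  }
})

test_that("likelihood ratio test matches the chi-square(4) reference", {
  mk_fit <- function(model, lnl) structure(
    list(model = model, rates = rep(1, 8), lnL = lnl, converged = TRUE),
    class = "fit_result")
  lrt <- lrt_pair(mk_fit("pair_independent", -10), mk_fit("pair_dependent", -10))
  expect_equal(lrt$D, 0)
  expect_equal(lrt$p, 1)
  # 0.99-quantile of chi-square(4)
  lrt <- lrt_pair(mk_fit("pair_independent", -10),
                  mk_fit("pair_dependent", -10 + 13.2767 / 2))
  expect_equal(lrt$p, 0.01, tolerance = 1e-3)
  # numerical noise below zero is clipped
  lrt <- lrt_pair(mk_fit("pair_independent", -10),
                  mk_fit("pair_dependent", -10 - 1e-9))
  expect_equal(lrt$D, 0)
  expect_error(lrt_pair(mk_fit("pair_independent", -10),
                        structure(list(model = "pair_dependent", lnL = -9,
                                       converged = FALSE),
                                  class = "fit_result")),
               "converged")
})

test_that("RQ reflects stationary concordance of the fitted pair model", {
  mk_dep <- function(rates) structure(
    list(model = "pair_dependent",
         rates = setNames(rates, c("alpha1", "alpha2", "beta1", "beta2",
                                   "gamma1", "gamma2", "delta1", "delta2")),
         lnL = -1, converged = TRUE),
    class = "fit_result")
  # independent constraint with all rates equal -> uniform -> RQ = 0.5
  expect_equal(as.numeric(rq_statistic(mk_dep(rep(1, 8)))), 0.5,
               tolerance = 1e-10)
  # strong positive coupling concentrates mass on 00/11
  expect_gt(as.numeric(rq_statistic(mk_dep(c(0.1, 10, 0.1, 10,
                                             10, 0.1, 10, 0.1)))), 0.9)
  # strong anti-coupling
  expect_lt(as.numeric(rq_statistic(mk_dep(c(10, 0.1, 10, 0.1,
                                             0.1, 10, 0.1, 10)))), 0.5)
})

test_that("gain/loss summary recovers ratios and symmetries", {
  tree <- simulate_tree(48, seed = 9)
  set.seed(10)
  m <- matrix(0L, 48, 12, dimnames = list(tree$tip.label,
                                          sprintf("T%02d", 1:12)))
  Q <- rate_matrix2(0.4, 2)
  for (j in 1:12) m[, j] <- simulate_trait(tree, Q, root = "stationary")
  m <- m[, colSums(m) > 0 & colSums(m) < 48, drop = FALSE]
  gl <- gain_loss_summary(trait_matrix(m, "GCF"), tree, seed = 5,
                          n_restarts = 3)
  expect_true(all(gl$per_trait$ratio[gl$per_trait$converged] > 0))
  expect_equal(gl$n_traits, sum(gl$per_trait$converged))

  # complementing every trait swaps q01 and q10: median ratio inverts
  gl_c <- gain_loss_summary(trait_matrix(1L - m, "GCF"), tree, seed = 5,
                            n_restarts = 3)
  expect_equal(gl_c$median_ratio, 1 / gl$median_ratio, tolerance = 0.2)

  # single informative trait: MAD = 0
  one <- gain_loss_summary(trait_matrix(m[, 1, drop = FALSE], "GCF"), tree,
                           seed = 5, n_restarts = 3)
  expect_equal(one$mad_ratio, 0)
  expect_error(gain_loss_summary(
    trait_matrix(matrix(0L, 48, 2, dimnames = list(tree$tip.label,
                                                   c("a", "b"))), "GCF"),
    tree), "both states")
})

test_that("pair fit agrees with an independent reference implementation", {
  skip_if_not_installed("phytools")
  tree <- simulate_tree(24, seed = 7)
  ab <- simulate_trait(tree, coupled_pair_rates(0.4, 2, 0.4, 2, 8),
                       root = 1, seed = 42)
  fi <- fit_model(tree, ab, "pair_independent", seed = 1, n_restarts = 5)
  fd <- fit_model(tree, ab, "pair_dependent", seed = 2, n_restarts = 5)
  fp <- suppressWarnings(phytools::fitPagel(
    tree, setNames(ab[, 1], rownames(ab)), setNames(ab[, 2], rownames(ab)),
    model = "ARD"))
  # same models, independently coded: lnLs agree to optimizer resolution
  expect_equal(fi$lnL, as.numeric(fp$independent.logL), tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(fd$lnL, as.numeric(fp$dependent.logL), tolerance = 0.05,
               ignore_attr = TRUE)
})
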