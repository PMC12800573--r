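#' Minimum parsimony change count of a binary trait on a tree
#'
#' Unit-cost small parsimony (Sankoff) on the rooted tree: the minimum
#' number of 0/1 state changes needed to explain the tip states. Used as
#' the observable eligibility criterion for the correlated-evolution test
#' (a pair is only testable when each trait shows at least two events of
#' gain or loss on the tree; e.g. a trait confined to one clade shows a
#' single gain and carries no information about repeated co-evolution).
#'
#' @param tree A `phylo` object (multifurcations allowed).
#' @param trait Named 0/1 vector over the tips.
#' @return Integer minimum number of changes.
#' @export
parsimony_changes <- function(tree, trait) {
  validate_phylogeny(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  miss <- setdiff(tr$tip.label, names(trait))
  if (length(miss)) stop("tips missing a state: ", paste(miss, collapse = ", "))
  v <- as.integer(trait[tr$tip.label])
  if (!all(v %in% c(0L, 1L))) stop("trait must be binary 0/1")
  n_node <- max(tr$edge)
  INF <- .Machine$integer.max %/% 4L
  cost <- matrix(0L, n_node, 2L)
  cost[seq_len(n_tip), ] <- INF
  cost[cbind(seq_len(n_tip), v + 1L)] <- 0L
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    add0 <- min(cost[ch, 1L], cost[ch, 2L] + 1L)
    add1 <- min(cost[ch, 2L], cost[ch, 1L] + 1L)
    cost[p, 1L] <- cost[p, 1L] + add0
    cost[p, 2L] <- cost[p, 2L] + add1
  }
  root <- n_tip + 1L
  min(cost[root, ])
}

#' Phylogeny-aware association screen over all GCF x MF pairs
#'
#' For every (GCF, MF) pair: eligibility requires at least `min_changes`
#' parsimony changes for each trait separately; eligible pairs are fitted
#' under the independent (4-rate) and dependent (8-rate) pair models,
#' compared by likelihood ratio test (chi-square, 4 df) and direction-
#' filtered by the stationary-concordance statistic RQ. A pair is called
#' `linked` iff it is eligible, `p < alpha` and `RQ >= rq_min`. Results
#' are deterministic given `seed` (each pair receives a derived seed).
#'
#' @param gcf,mf [trait_matrix()] objects sharing the tree's strains.
#' @param tree A `phylo` object.
#' @param alpha Significance level of the LRT (default 0.01).
#' @param rq_min Minimum RQ for a positive call (default 0.65).
#' @param min_changes Minimum parsimony changes per trait (default 2).
#' @param seed Base seed.
#' @param n_restarts Optimizer starts per fit (default 5).
#' @param p_adjust `"none"` (default, matching the plain alpha decision
#'   rule) or `"BH"` to apply a Benjamini-Hochberg correction across the
#'   converged eligible pairs before calling verdicts.
#' @return Data frame with one row per pair: `gcf_id`, `mf_id`,
#'   `eligible`, `changes_gcf`, `changes_mf`, `lnl_indep`, `lnl_dep`, `D`,
#'   `p`, `RQ`, `verdict` (`linked` / `not-linked` / `ineligible`),
#'   `method = "phylo"`, `converged`.
#' @export
associate_all <- function(gcf, mf, tree, alpha = 0.01, rq_min = 0.65,
                          min_changes = 2L, seed = 1L, n_restarts = 5L,
                          p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  check_matrix_tree(gcf, tree); check_matrix_tree(mf, tree)
  tree <- rescale_tree_depth(tree)
  ch_g <- vapply(colnames(gcf), function(j)
    parsimony_changes(tree, setNames(unclass(gcf)[, j], rownames(gcf))),
    integer(1L))
  ch_m <- vapply(colnames(mf), function(j)
    parsimony_changes(tree, setNames(unclass(mf)[, j], rownames(mf))),
    integer(1L))
  pairs <- expand.grid(gcf_id = colnames(gcf), mf_id = colnames(mf),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(pairs)
  res <- data.frame(pairs,
                    eligible = FALSE,
                    changes_gcf = ch_g[pairs$gcf_id],
                    changes_mf = ch_m[pairs$mf_id],
                    lnl_indep = NA_real_, lnl_dep = NA_real_,
                    D = NA_real_, p = NA_real_, RQ = NA_real_,
                    verdict = "ineligible", method = "phylo",
                    converged = NA, stringsAsFactors = FALSE)
  res$eligible <- res$changes_gcf >= min_changes & res$changes_mf >= min_changes
  for (i in which(res$eligible)) {
    pair_seed <- as.integer((seed + 7919 * i) %% 2147483647L)
    tm <- cbind(unclass(gcf)[, res$gcf_id[i]], unclass(mf)[, res$mf_id[i]])
    rownames(tm) <- rownames(gcf)
    fi <- fit_model(tree, tm, "pair_independent", seed = pair_seed,
                    n_restarts = n_restarts, rescale = FALSE)
    fd <- fit_model(tree, tm, "pair_dependent", seed = pair_seed + 1L,
                    n_restarts = n_restarts, rescale = FALSE,
                    init_rates = if (fi$converged)
                      expand_independent_rates(fi$rates) else NULL)
    if (!fi$converged || !fd$converged) {
      res$converged[i] <- FALSE
      res$verdict[i] <- NA_character_
      next
    }
    lrt <- lrt_pair(fi, fd)
    rq <- rq_statistic(fd)
    res$converged[i] <- TRUE
    res$lnl_indep[i] <- fi$lnL
    res$lnl_dep[i] <- fd$lnL
    res$D[i] <- lrt$D
    res$p[i] <- lrt$p
    res$RQ[i] <- as.numeric(rq)
    res$verdict[i] <- if (lrt$p < alpha && rq >= rq_min) "linked"
                      else "not-linked"
  }
  if (p_adjust == "BH") {
    done <- which(res$eligible & !is.na(res$p))
    res$p[done] <- stats::p.adjust(res$p[done], method = "BH")
    res$verdict[done] <- ifelse(res$p[done] < alpha &
                                  res$RQ[done] >= rq_min,
                                "linked", "not-linked")
  }
  res
}

# map fitted independent rates (gain_a, gain_b, loss_a, loss_b) onto the
# 8-rate dependent parameterization
expand_independent_rates <- function(r) {
  c(r[["gain_a"]], r[["gain_a"]], r[["gain_b"]], r[["gain_b"]],
    r[["loss_a"]], r[["loss_a"]], r[["loss_b"]], r[["loss_b"]])
}

check_matrix_tree <- function(m, tree) {
  if (!setequal(rownames(m), tree$tip.label))
    stop("matrix strains do not match tree tips; run validate_dataset() first")
  invisible(TRUE)
}

#' Chi-squared comparator screen (phylogeny ignored)
#'
#' Per (GCF, MF) pair, a 2x2 contingency table of presence/absence over
#' strains is scored with the Pearson chi-square statistic (Yates
#' continuity correction by default, mirroring the conventional 2x2
#' implementation). A pair is called `linked` iff `p < alpha` and the
#' observed co-presence exceeds its expectation (direction filter, so the
#' comparator reports positive associations only, like RQ). Pairs with a
#' constant trait are degenerate and called `not-linked`.
#'
#' @param gcf,mf [trait_matrix()] objects over the same strains.
#' @param alpha Significance level (default 0.01).
#' @param correct Apply the continuity correction (default TRUE).
#' @param direction_filter Require co-presence above expectation
#'   (default TRUE).
#' @return Data frame per pair: `gcf_id`, `mf_id`, `statistic`, `p`,
#'   `co_presence`, `expected_co_presence`, `verdict`,
#'   `method = "chisq"`, `degenerate`.
#' @export
chisq_screen <- function(gcf, mf, alpha = 0.01, correct = TRUE,
                         direction_filter = TRUE) {
  if (!setequal(rownames(gcf), rownames(mf)))
    stop("matrices cover different strain sets")
  G <- unclass(gcf)[sort(rownames(gcf)), , drop = FALSE]
  M <- unclass(mf)[rownames(G), , drop = FALSE]
  S <- nrow(G)
  n11 <- crossprod(G, M)                       # co-presence counts
  rg <- colSums(G); rm_ <- colSums(M)
  n1g <- matrix(rg, length(rg), length(rm_))
  n1m <- matrix(rm_, length(rg), length(rm_), byrow = TRUE)
  n10 <- n1g - n11
  n01 <- n1m - n11
  n00 <- S - n1g - n1m + n11
  e11 <- n1g * n1m / S
  det <- abs(n11 * n00 - n10 * n01)
  if (correct) det <- pmax(0, det - S / 2)
  denom <- n1g * (S - n1g) * n1m * (S - n1m)
  stat <- ifelse(denom > 0, S * det^2 / denom, NA_real_)
  pval <- pchisq(stat, df = 1L, lower.tail = FALSE)
  degen <- denom == 0
  linked <- !degen & !is.na(pval) & pval < alpha &
    (!direction_filter | n11 > e11)
  idx <- expand.grid(gi = seq_along(rg), mi = seq_along(rm_),
                     KEEP.OUT.ATTRS = FALSE)
  data.frame(gcf_id = colnames(G)[idx$gi], mf_id = colnames(M)[idx$mi],
             statistic = stat[cbind(idx$gi, idx$mi)],
             p = pval[cbind(idx$gi, idx$mi)],
             co_presence = n11[cbind(idx$gi, idx$mi)],
             expected_co_presence = e11[cbind(idx$gi, idx$mi)],
             verdict = ifelse(linked[cbind(idx$gi, idx$mi)], "linked",
                              "not-linked"),
             method = "chisq",
             degenerate = degen[cbind(idx$gi, idx$mi)],
             stringsAsFactors = FALSE)
}

#' Evaluate screen results against a catalog of known pairs
#'
#' For each known compound with cognate pair (g*, m*): `correct` iff
#' (g*, m*) is called linked; every linked pair (g, m*) with `g != g*`
#' counts one false positive. Linked pairs whose MF is not in the catalog
#' are ignored. `predicted` records whether the screen linked any GCF to
#' the compound's MF (used by [fold_reduction()]).
#'
#' @param results A results data frame from [associate_all()] or
#'   [chisq_screen()].
#' @param catalog A [known_pair_catalog()]; ids must resolve against the
#'   results' id universe.
#' @return An `evaluation_summary`: list with `per_compound` (data frame:
#'   compound, correct, false_positives, predicted), `correct_total`,
#'   `false_positive_total`, `method`.
#' @export
evaluate_known_pairs <- function(results, catalog) {
  stopifnot(inherits(catalog, "known_pair_catalog"))
  bad_g <- setdiff(catalog$gcf_id, unique(results$gcf_id))
  bad_m <- setdiff(catalog$mf_id, unique(results$mf_id))
  if (length(bad_g) || length(bad_m))
    stop("catalog ids not present in results: ",
         paste(c(bad_g, bad_m), collapse = ", "))
  linked <- results[!is.na(results$verdict) & results$verdict == "linked", ,
                    drop = FALSE]
  per <- do.call(rbind, lapply(seq_len(nrow(catalog)), function(i) {
    g <- catalog$gcf_id[i]; m <- catalog$mf_id[i]
    hits <- linked[linked$mf_id == m, , drop = FALSE]
    data.frame(compound = catalog$compound[i],
               correct = g %in% hits$gcf_id,
               false_positives = sum(hits$gcf_id != g),
               predicted = nrow(hits) > 0L,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_compound = per,
                 correct_total = sum(per$correct),
                 false_positive_total = sum(per$false_positives),
                 method = unique(results$method)),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("<evaluation_summary (%s): %d correct, %d false positives over %d compounds>\n",
              paste(x$method, collapse = "/"), x$correct_total,
              x$false_positive_total, nrow(x$per_compound)))
  print(x$per_compound)
  invisible(x)
}

#' Fold reduction in false positives relative to a comparator
#'
#' Computed over the compounds the focal (phylogeny-aware) screen actually
#' made predictions for: compounds where it predicted nothing are excluded
#' from the comparator's false-positive baseline, so the ratio reflects
#' the pairs both methods assessed.
#'
#' @param focal,comparator `evaluation_summary` objects over the same
#'   catalog (focal is typically the phylogeny-aware screen).
#' @return Ratio of comparator to focal false positives over the assessed
#'   compounds (`Inf` when the focal screen made no false positives).
#' @export
fold_reduction <- function(focal, comparator) {
  stopifnot(inherits(focal, "evaluation_summary"),
            inherits(comparator, "evaluation_summary"))
  fc <- focal$per_compound
  cc <- comparator$per_compound
  if (!identical(fc$compound, cc$compound))
    stop("summaries cover different compounds")
  assessed <- fc$predicted
  num <- sum(cc$false_positives[assessed])
  den <- sum(fc$false_positives[assessed])
  if (den == 0) return(Inf)
  num / den
}

#' Permutation control: shuffle MF strain assignments and re-screen
#'
#' Each permutation reassigns the MF matrix rows to strains by a seeded
#' random bijection (column sums preserved), re-runs the requested
#' screen(s) and evaluates against the catalog. Planted or real signal
#' should be destroyed: the expected number of correct calls is ~0.
#'
#' @param gcf,mf [trait_matrix()] objects.
#' @param tree A `phylo` object.
#' @param catalog A [known_pair_catalog()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Base seed; permutation `i` uses `seed + i`.
#' @param methods Screens to run: subset of `c("phylo", "chisq")`.
#' @param ... Further arguments passed to [associate_all()].
#' @return List of per-permutation records: `seed`, `permutation`, and an
#'   `evaluation_summary` per method.
#' @export
permutation_control <- function(gcf, mf, tree, catalog, n_perm = 20L,
                                seed = 1L, methods = c("phylo", "chisq"),
                                ...) {
  stopifnot(n_perm >= 1L)
  methods <- match.arg(methods, several.ok = TRUE)
  out <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    pseed <- as.integer((seed + i) %% 2147483647L)
    set.seed(pseed)
    perm <- sample(nrow(mf))
    mperm <- unclass(mf)[perm, , drop = FALSE]
    rownames(mperm) <- rownames(mf)
    mperm <- trait_matrix(mperm, "MF")
    rec <- list(seed = pseed, permutation = perm)
    if ("phylo" %in% methods) {
      res <- associate_all(gcf, mperm, tree, seed = pseed, ...)
      rec$phylo <- evaluate_known_pairs(res, catalog)
    }
    if ("chisq" %in% methods) {
      res <- chisq_screen(gcf, mperm)
      rec$chisq <- evaluate_known_pairs(res, catalog)
    }
    out[[i]] <- rec
  }
  out
}
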