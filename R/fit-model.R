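#' Maximum-likelihood fit of a CTMC trait model on a tree
#'
#' Fits one of three models by bounded multi-start maximum likelihood:
#' * `"single"` — one binary trait, 2 rates (gain `q01`, loss `q10`);
#' * `"pair_independent"` — two binary traits evolving independently,
#'   4 rates;
#' * `"pair_dependent"` — two binary traits with partner-dependent rates,
#'   8 rates (see [rate_matrix4()]).
#'
#' Optimization is quasi-Newton (`L-BFGS-B`) on log-rates with box bounds
#' `[1e-6, 1e3]` on the depth-rescaled tree (mean root-to-tip path = 1;
#' see [rescale_tree_depth()]); rate ratios are invariant to that scaling.
#' One fixed start is complemented by `n_restarts - 1` log-uniform random
#' starts; results are deterministic given `seed`. Ties between restarts
#' are broken by highest log-likelihood, then lowest L2 norm of the
#' log-rate vector.
#'
#' @param tree A `phylo` object.
#' @param traits For `"single"`: a named 0/1 vector over tips. For pair
#'   models: a two-column 0/1 matrix (columns A = GCF, B = MF) with row
#'   names = tips, or a list of two named vectors.
#' @param model Model kind.
#' @param seed Integer seed for restart draws.
#' @param n_restarts Number of optimizer starts (default 5).
#' @param rate_bounds Lower/upper bounds on each rate (default
#'   `c(1e-6, 1e3)`).
#' @param root_prior Passed to the likelihood (default `"uniform"`).
#' @param rescale Rescale the tree to unit mean depth first (default TRUE).
#' @param init_rates Optional rate vector (natural scale, model order) used
#'   as an additional optimizer start — e.g. the expanded independent-fit
#'   rates when fitting the dependent model, which guarantees the nested
#'   model's optimum is attainable.
#' @return A `fit_result`: list with `model`, `rates` (named), `lnL`,
#'   `converged`, `degenerate`, `restarts`, `seed`, `depth_scale`.
#' @export
fit_model <- function(tree, traits, model = c("single", "pair_independent",
                                              "pair_dependent"),
                      seed = 1L, n_restarts = 5L,
                      rate_bounds = c(1e-6, 1e3), root_prior = "uniform",
                      rescale = TRUE, init_rates = NULL) {
  model <- match.arg(model)
  validate_phylogeny(tree)
  depth_scale <- 1
  if (rescale) {
    tree <- rescale_tree_depth(tree)
    depth_scale <- attr(tree, "depth_scale")
  }
  cache <- tree_cache(tree)

  if (model == "single") {
    states <- traits
    k <- 2L
    p <- 2L
    par_names <- c("q01", "q10")
    build_Q <- function(r) rate_matrix2(r[1L], r[2L])
    degenerate <- length(unique(states[cache$tips])) < 2L
  } else {
    ab <- as_pair_traits(traits, cache$tips)
    states <- pair_states(ab$a, ab$b)
    k <- 4L
    if (model == "pair_independent") {
      p <- 4L
      par_names <- c("gain_a", "gain_b", "loss_a", "loss_b")
      build_Q <- function(r) rate_matrix4_independent(r[1L], r[3L],
                                                      r[2L], r[4L])
    } else {
      p <- 8L
      par_names <- c("alpha1", "alpha2", "beta1", "beta2",
                     "gamma1", "gamma2", "delta1", "delta2")
      build_Q <- function(r) rate_matrix4(r[1L], r[2L], r[3L], r[4L],
                                          r[5L], r[6L], r[7L], r[8L])
    }
    degenerate <- length(unique(ab$a[cache$tips])) < 2L ||
      length(unique(ab$b[cache$tips])) < 2L
  }
  idx0 <- tip_state_index_cache(cache, states, k)
  lb <- log(rate_bounds[1L]); ub <- log(rate_bounds[2L])
  model_code <- switch(model, single = 1L, pair_independent = 2L,
                       pair_dependent = 3L)
  # uniform / fixed priors do not depend on Q: use the all-C++ objective
  fast <- identical(root_prior, "uniform") || is.numeric(root_prior)
  if (fast) {
    prior_vec <- if (is.numeric(root_prior)) as.numeric(root_prior)
                 else rep(1 / k, k)
    negll <- function(lr)
      cpp_negll(exp(lr), model_code, cache$edge, cache$len, cache$n_tip,
                idx0, prior_vec)
  } else {
    negll <- function(lr) {
      Q <- build_Q(exp(lr))
      prior <- resolve_root_prior(root_prior, Q)
      min(-cached_loglik(cache, idx0, unname(Q), prior), 1e10)
    }
  }

  set.seed(as.integer(seed %% .Machine$integer.max))
  starts <- matrix(log(0.5), 1L, p)
  if (n_restarts > 1L)
    starts <- rbind(starts,
                    matrix(runif((n_restarts - 1L) * p, log(1e-3), log(1e2)),
                           ncol = p))
  if (!is.null(init_rates)) {
    stopifnot(length(init_rates) == p, all(init_rates > 0))
    starts <- rbind(pmin(pmax(log(init_rates), lb), ub), starts)
  }
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], negll, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(factr = 1e-8 / .Machine$double.eps, maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 &&
         sum(fit$par^2) < sum(best$par^2)))
      best <- fit
  }
  if (is.null(best)) {
    return(structure(list(model = model, rates = setNames(rep(NA_real_, p),
                                                          par_names),
                          lnL = NA_real_, converged = FALSE,
                          degenerate = degenerate, restarts = n_restarts,
                          seed = seed, depth_scale = depth_scale),
                     class = "fit_result"))
  }
  structure(list(model = model,
                 rates = setNames(exp(best$par), par_names),
                 lnL = -best$value, converged = TRUE,
                 degenerate = degenerate, restarts = n_restarts,
                 seed = seed, depth_scale = depth_scale),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s: lnL = %.4f, converged = %s%s>\n", x$model,
              x$lnL, x$converged, if (x$degenerate) ", degenerate" else ""))
  print(signif(x$rates, 4))
  invisible(x)
}

as_pair_traits <- function(traits, tips) {
  if (is.list(traits) && !is.data.frame(traits) && length(traits) == 2L)
    return(list(a = traits[[1L]], b = traits[[2L]]))
  m <- as.matrix(traits)
  if (ncol(m) != 2L) stop("pair models need two trait columns")
  if (is.null(rownames(m))) stop("pair traits need tip row names")
  list(a = setNames(m[, 1L], rownames(m)), b = setNames(m[, 2L], rownames(m)))
}

tip_state_index_cache <- function(cache, states, k) {
  miss <- setdiff(cache$tips, names(states))
  if (length(miss))
    stop("tips missing a state: ", paste(miss, collapse = ", "))
  v <- as.integer(states[cache$tips])
  if (k == 2L) v else v - 1L
}

#' Gain/loss coefficient summary over all traits of a matrix
#'
#' Fits the single-trait model to every trait with both states present and
#' summarizes the per-trait gain/loss ratio `r = q01 / q10` by its median
#' and median absolute deviation (plain MAD, no consistency constant).
#' Non-converged and degenerate fits are excluded.
#'
#' @param matrix A [trait_matrix()].
#' @param tree A `phylo` object over the matrix's strains.
#' @param seed Base seed; trait `i` is fitted with `seed + i`.
#' @param n_restarts Optimizer starts per trait (default 5).
#' @return List with `per_trait` (data frame: trait, q01, q10, ratio,
#'   converged), `median_ratio`, `mad_ratio`, `n_traits`.
#' @export
gain_loss_summary <- function(matrix, tree, seed = 1L, n_restarts = 5L) {
  informative <- colnames(matrix)[apply(matrix, 2L, function(v)
    length(unique(v)) == 2L)]
  if (!length(informative))
    stop("no trait has both states present; nothing to summarize")
  tree <- rescale_tree_depth(tree)
  rows <- lapply(seq_along(informative), function(i) {
    tr <- informative[i]
    v <- setNames(unclass(matrix)[, tr], rownames(matrix))
    f <- fit_model(tree, v, "single", seed = seed + i,
                   n_restarts = n_restarts, rescale = FALSE)
    data.frame(trait = tr, q01 = f$rates[["q01"]], q10 = f$rates[["q10"]],
               ratio = f$rates[["q01"]] / f$rates[["q10"]],
               converged = f$converged, stringsAsFactors = FALSE)
  })
  per_trait <- do.call(rbind, rows)
  ok <- per_trait$converged & is.finite(per_trait$ratio)
  if (!any(ok)) stop("no converged single-trait fits")
  list(per_trait = per_trait,
       median_ratio = median(per_trait$ratio[ok]),
       mad_ratio = mad(per_trait$ratio[ok], constant = 1),
       n_traits = sum(ok))
}

#' Stationary-concordance statistic (RQ) of a dependent pair fit
#'
#' RQ is the probability mass the fitted dependent model places on the
#' concordant states at stationarity: `RQ = pi(0,0) + pi(1,1)`. Values
#' above 0.5 indicate positive association of the two traits (they tend to
#' be present, or absent, together in the long run), values below 0.5
#' anti-association. Used with the default threshold 0.65 to keep only
#' positively associated pairs.
#'
#' @param dep A converged `"pair_dependent"` [fit_model()] result.
#' @return RQ in \[0, 1\]; attribute `restricted = TRUE` flags a
#'   near-reducible fitted generator.
#' @export
rq_statistic <- function(dep) {
  stopifnot(inherits(dep, "fit_result"), dep$model == "pair_dependent")
  if (!dep$converged) stop("dependent fit did not converge")
  Q <- do.call(rate_matrix4, as.list(unname(dep$rates)))
  pi_ <- stationary_distribution(Q)
  rq <- unname(pi_["00"] + pi_["11"])
  if (isTRUE(attr(pi_, "restricted"))) attr(rq, "restricted") <- TRUE
  rq
}

#' Likelihood ratio test between independent and dependent pair fits
#'
#' `D = 2 (lnL_dep - lnL_indep)`, clipped at 0 against numerical noise;
#' p-value from the upper tail of the chi-square distribution with 4
#' degrees of freedom (8 - 4 free rates).
#'
#' @param indep A converged `"pair_independent"` fit.
#' @param dep A converged `"pair_dependent"` fit on the same data.
#' @return List with `D` and `p`.
#' @export
lrt_pair <- function(indep, dep) {
  stopifnot(inherits(indep, "fit_result"), inherits(dep, "fit_result"),
            indep$model == "pair_independent",
            dep$model == "pair_dependent")
  if (!indep$converged || !dep$converged)
    stop("both fits must have converged")
  D <- max(0, 2 * (dep$lnL - indep$lnL))
  list(D = D, p = pchisq(D, df = 4L, lower.tail = FALSE))
}
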