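#' Incidence-based rarefaction and extrapolation of trait richness
#'
#' Sample-based (incidence) rarefaction of the expected number of traits
#' (e.g. GCFs) observed in `t` of the `T` strains, with extrapolation
#' beyond `T` driven by the Chao2 estimate of undetected richness.
#'
#' Rarefaction uses the hypergeometric expectation
#' `S(t) = S_obs - sum_i choose(T - Y_i, t) / choose(T, t)` over traits
#' with incidence `Y_i >= 1`. The Chao2 asymptote is
#' `S_obs + ((T-1)/T) * Q1^2 / (2 Q2)` with uniques `Q1` and duplicates
#' `Q2`, replaced by the bias-corrected form
#' `S_obs + ((T-1)/T) * Q1 (Q1 - 1) / 2` when `Q2 = 0`. Extrapolated
#' values approach the asymptote geometrically in the number of added
#' strains. Traits never observed (all-zero columns) do not contribute.
#'
#' @param matrix A [trait_matrix()] (or binary matrix) of strains x traits.
#' @param extrapolate_to Largest sample size of the curve (default `T`,
#'   i.e. no extrapolation); must be at least the number of strains.
#' @param sizes Optional integer vector of sample sizes; default `1:T`
#'   plus `T+1 .. extrapolate_to`.
#' @return An `incidence_curve`: list with `curve` (data frame: size,
#'   q0_estimate, segment = rarefied/extrapolated), `s_obs`, `chao2`,
#'   `q1`, `q2`, `n_samples`.
#' @export
incidence_rarefaction <- function(matrix, extrapolate_to = NULL,
                                  sizes = NULL) {
  m <- unclass(matrix)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty incidence matrix")
  T_ <- nrow(m)
  Y <- colSums(m)
  Y <- Y[Y >= 1L]
  s_obs <- length(Y)
  if (s_obs == 0L) stop("no trait observed in any strain")
  q1 <- sum(Y == 1L)
  q2 <- sum(Y == 2L)
  q0_hat <- if (q2 > 0) ((T_ - 1) / T_) * q1^2 / (2 * q2)
            else ((T_ - 1) / T_) * q1 * (q1 - 1) / 2
  chao2 <- s_obs + q0_hat
  if (is.null(extrapolate_to)) extrapolate_to <- T_
  if (extrapolate_to < T_)
    stop("extrapolate_to must be >= the number of strains (", T_, ")")
  if (is.null(sizes)) sizes <- seq_len(extrapolate_to)
  sizes <- sort(unique(as.integer(sizes)))
  est <- vapply(sizes, function(t) {
    if (t <= T_) {
      # expected richness in t of T strains (hypergeometric)
      s_obs - sum(exp(lchoose(T_ - Y, t) - lchoose(T_, t)))
    } else {
      t_star <- t - T_
      if (q1 == 0 || q0_hat == 0) s_obs
      else s_obs + q0_hat * (1 - (1 - q1 / (q1 + T_ * q0_hat))^t_star)
    }
  }, numeric(1L))
  structure(list(curve = data.frame(size = sizes, q0_estimate = est,
                                    segment = ifelse(sizes <= T_,
                                                     "rarefied",
                                                     "extrapolated"),
                                    stringsAsFactors = FALSE),
                 s_obs = s_obs, chao2 = chao2, q1 = q1, q2 = q2,
                 n_samples = T_),
            class = "incidence_curve")
}

#' @export
print.incidence_curve <- function(x, ...) {
  cat(sprintf("<incidence_curve: %d strains, S_obs = %d, Chao2 = %.2f (Q1 = %d, Q2 = %d)>\n",
              x$n_samples, x$s_obs, x$chao2, x$q1, x$q2))
  invisible(x)
}

#' Write an incidence curve to TSV
#' @param x An `incidence_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_incidence_curve <- function(x, path) {
  write.table(x$curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
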