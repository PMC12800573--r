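#' Two-state rate matrix for a single binary trait
#'
#' Generator of a continuous-time Markov chain on states \{0 = absent,
#' 1 = present\}: `q01` is the gain coefficient (0 to 1), `q10` the loss
#' coefficient (1 to 0), both per unit branch length.
#'
#' @param q01,q10 Positive rates.
#' @return A 2x2 generator matrix (rows sum to 0).
#' @export
rate_matrix2 <- function(q01, q10) {
  stopifnot(is.finite(q01), is.finite(q10), q01 >= 0, q10 >= 0)
  matrix(c(-q01, q01, q10, -q10), 2L, 2L, byrow = TRUE,
         dimnames = list(c("0", "1"), c("0", "1")))
}

#' Eight-rate generator for a pair of binary traits
#'
#' States are ordered `(0,0), (0,1), (1,0), (1,1)` for the pair
#' (A = GCF, B = MF). The eight rates are the single-trait transitions
#' conditional on the partner's state; simultaneous changes of both traits
#' have rate 0:
#' * `alpha1 = q(00->10)`, `alpha2 = q(01->11)` — gain of A;
#' * `beta1 = q(00->01)`, `beta2 = q(10->11)` — gain of B;
#' * `gamma1 = q(10->00)`, `gamma2 = q(11->01)` — loss of A;
#' * `delta1 = q(01->00)`, `delta2 = q(11->10)` — loss of B.
#'
#' The independent submodel is the constraint `alpha1 = alpha2`,
#' `beta1 = beta2`, `gamma1 = gamma2`, `delta1 = delta2`.
#'
#' @param alpha1,alpha2,beta1,beta2,gamma1,gamma2,delta1,delta2 Rates
#'   (non-negative, per unit branch length).
#' @return A 4x4 generator matrix.
#' @export
rate_matrix4 <- function(alpha1, alpha2, beta1, beta2,
                         gamma1, gamma2, delta1, delta2) {
  r <- c(alpha1, alpha2, beta1, beta2, gamma1, gamma2, delta1, delta2)
  stopifnot(all(is.finite(r)), all(r >= 0))
  Q <- matrix(0, 4L, 4L,
              dimnames = rep(list(c("00", "01", "10", "11")), 2L))
  Q["00", "10"] <- alpha1; Q["01", "11"] <- alpha2
  Q["00", "01"] <- beta1;  Q["10", "11"] <- beta2
  Q["10", "00"] <- gamma1; Q["11", "01"] <- gamma2
  Q["01", "00"] <- delta1; Q["11", "10"] <- delta2
  diag(Q) <- -rowSums(Q)
  Q
}

#' Independent-evolution generator for a trait pair
#' @param gain_a,loss_a,gain_b,loss_b Single-trait rates of the two traits.
#' @return A 4x4 generator (the constrained submodel of [rate_matrix4()]).
#' @export
rate_matrix4_independent <- function(gain_a, loss_a, gain_b, loss_b) {
  rate_matrix4(gain_a, gain_a, gain_b, gain_b,
               loss_a, loss_a, loss_b, loss_b)
}

#' Transition probability matrix P = exp(Qt)
#'
#' @param Q A generator matrix (2x2 or 4x4).
#' @param t Branch length, `t >= 0`.
#' @return Stochastic matrix of the same dimension.
#' @export
transition_probabilities <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("branch length t must be a single finite value >= 0")
  P <- cpp_transition_matrix(unname(as.matrix(Q)), t)
  dimnames(P) <- dimnames(Q)
  P
}

#' Stationary distribution of a generator
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` via the singular value decomposition.
#' If numerical clipping of negative components was needed (near-reducible
#' generators with rates at the bounds), the result carries attribute
#' `restricted = TRUE`.
#'
#' @param Q A generator matrix.
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(Q) {
  s <- svd(t(unname(as.matrix(Q))))
  x <- s$v[, ncol(Q)]
  if (sum(x) < 0) x <- -x
  restricted <- any(x < -1e-8)
  x[x < 0] <- 0
  pi_ <- x / sum(x)
  names(pi_) <- rownames(Q)
  if (restricted) attr(pi_, "restricted") <- TRUE
  pi_
}

# Map named tip states to the 0-based indices the C++ pruning expects.
# states: named vector with values 0/1 (k = 2) or 1..4 (k = 4).
tip_state_index <- function(tree, states, k) {
  if (is.null(names(states))) stop("tip states must be named by tip label")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("tips missing a state: ", paste(miss, collapse = ", "))
  v <- states[tree$tip.label]
  if (any(is.na(v))) stop("NA tip state")
  if (k == 2L) {
    if (!all(v %in% c(0, 1))) stop("2-state tip values must be 0/1")
    as.integer(v)
  } else {
    if (!all(v %in% 1:4)) stop("4-state tip values must be in 1..4")
    as.integer(v) - 1L
  }
}

#' Combine two binary trait vectors into pair states
#'
#' @param a,b Named 0/1 vectors over the same tips (A = GCF, B = MF).
#' @return Named vector of pair-state indices 1..4 in the order
#'   `(0,0), (0,1), (1,0), (1,1)`.
#' @export
pair_states <- function(a, b) {
  if (!setequal(names(a), names(b))) stop("trait vectors cover different tips")
  b <- b[names(a)]
  setNames(as.integer(2L * a + b + 1L), names(a))
}

#' Log-likelihood of tip states on a tree under a CTMC
#'
#' Felsenstein pruning over a rooted, possibly multifurcating tree. The
#' root prior defaults to uniform over states (configurable to the
#' stationary distribution of `Q`). Zero-length branches contribute an
#' identity transition. An all-but-impossible configuration (likelihood
#' underflowing to 0) is guarded as the sentinel `-1e308`.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param states Named tip states: 0/1 for a 2x2 generator, 1..4 pair
#'   indices (see [pair_states()]) for a 4x4 generator.
#' @param Q Generator matrix.
#' @param root_prior `"uniform"` (default), `"stationary"`, or a numeric
#'   probability vector over states.
#' @return Natural-log likelihood.
#' @export
tree_log_likelihood <- function(tree, states, Q, root_prior = "uniform") {
  validate_phylogeny(tree)
  k <- nrow(Q)
  prior <- resolve_root_prior(root_prior, Q)
  tr <- ape::reorder.phylo(tree, "postorder")
  idx <- tip_state_index(tr, states, k)
  cpp_tree_loglik(matrix(as.integer(tr$edge), ncol = 2L), tr$edge.length,
                  length(tr$tip.label), idx, unname(as.matrix(Q)), prior)
}

resolve_root_prior <- function(root_prior, Q) {
  k <- nrow(Q)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k, all(root_prior >= 0),
              abs(sum(root_prior) - 1) < 1e-8)
    return(as.numeric(root_prior))
  }
  switch(match.arg(root_prior, c("uniform", "stationary")),
         uniform = rep(1 / k, k),
         stationary = as.numeric(stationary_distribution(Q)))
}

# Precomputed tree encoding for repeated likelihood evaluations (hot loop
# of the optimizer): postorder edges, lengths and tip index lookup.
tree_cache <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = matrix(as.integer(tr$edge), ncol = 2L),
       len = tr$edge.length, n_tip = length(tr$tip.label),
       tips = tr$tip.label)
}

cached_loglik <- function(cache, idx0, Q, prior) {
  cpp_tree_loglik(cache$edge, cache$len, cache$n_tip, idx0, Q, prior)
}
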