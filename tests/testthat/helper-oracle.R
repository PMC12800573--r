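# Independent oracles used to check the likelihood engine. Nothing here
# shares code with the package's C++ path.

# Matrix exponential by scaling-and-squaring of the truncated Taylor
# series (plain R; independent of the Armadillo implementation).
oracle_expm <- function(Q, t) {
  A <- Q * t
  m <- max(1, ceiling(log2(max(1, norm(A, "1")))))
  A <- A / 2^m
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (n in 1:30) {
    term <- term %*% A / n
    P <- P + term
  }
  for (i in seq_len(m)) P <- P %*% P
  P
}

# Brute-force tree likelihood: sum over all internal-node state
# assignments of prior(root) * prod over edges P[s_par, s_child](t).
oracle_tree_lik <- function(tree, states, Q, prior) {
  k <- nrow(Q)
  n_tip <- length(tree$tip.label)
  edges <- tree$edge
  internal <- sort(unique(edges[, 1L]))
  root <- n_tip + 1L
  P <- lapply(seq_len(nrow(edges)), function(e)
    oracle_expm(Q, tree$edge.length[e]))
  tip_state <- states[tree$tip.label]
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_ <- integer(max(edges))
    assign_[internal] <- grid[g, ]
    assign_[seq_len(n_tip)] <- tip_state
    p <- prior[assign_[root]]
    for (e in seq_len(nrow(edges)))
      p <- p * P[[e]][assign_[edges[e, 1L]], assign_[edges[e, 2L]]]
    total <- total + p
  }
  total
}

# Random tree with branch lengths for property tests (may be multifurcating
# when collapse = TRUE).
oracle_random_tree <- function(n_tips, seed, collapse = FALSE) {
  set.seed(seed)
  tree <- ape::rtree(n_tips)
  tree$edge.length <- runif(nrow(tree$edge), 0.05, 1.5)
  if (collapse && n_tips >= 4L) {
    tree <- ape::di2multi(tree, tol = 0.2)
    tree$edge.length <- pmax(tree$edge.length, 0.05)
  }
  tree
}

random_rates2 <- function(seed) {
  set.seed(seed)
  exp(runif(2, log(0.1), log(5)))
}

random_rates4 <- function(seed) {
  set.seed(seed)
  exp(runif(8, log(0.1), log(5)))
}

# tip states 1..k named by tip, uniform random
random_states <- function(tree, k, seed) {
  set.seed(seed)
  setNames(sample.int(k, length(tree$tip.label), replace = TRUE),
           tree$tip.label)
}
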