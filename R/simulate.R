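#' Simulate a Yule tree over n strains
#'
#' Pure-birth tree conditioned on `n` tips (via [ape::rphylo()]), rescaled
#' to unit mean root-to-tip depth so that simulation and fitting rates are
#' on the same per-unit-depth scale.
#'
#' @param n Number of tips (>= 2).
#' @param rate Birth rate (default 1; only the topology/relative depths
#'   matter after rescaling).
#' @param seed Integer seed.
#' @return A `phylo` object with tips `t1 .. tn`.
#' @export
simulate_tree <- function(n, rate = 1, seed = 1L) {
  if (n < 2L) stop("need n >= 2 tips")
  set.seed(as.integer(seed %% .Machine$integer.max))
  tree <- ape::rphylo(n, birth = rate, death = 0)
  tree$tip.label <- paste0("t", seq_len(n))
  rescale_tree_depth(tree)
}

# One CTMC realization along a branch: exact waiting-time simulation.
sim_edge <- function(state, Q, t) {
  k <- nrow(Q)
  remaining <- t
  repeat {
    out_rate <- -Q[state, state]
    if (out_rate <= 0) return(state)
    w <- rexp(1L, out_rate)
    if (w >= remaining) return(state)
    remaining <- remaining - w
    probs <- Q[state, ]
    probs[state] <- 0
    state <- sample.int(k, 1L, prob = probs)
  }
}

#' Forward-simulate a trait (or trait pair) on a tree
#'
#' The root state is drawn from the requested prior (or fixed), then
#' states evolve edge by edge by exact CTMC waiting-time sampling.
#'
#' @param tree A `phylo` object.
#' @param Q A 2x2 or 4x4 generator ([rate_matrix2()] / [rate_matrix4()]).
#' @param root `"stationary"` (default), `"uniform"`, a probability
#'   vector, or a fixed state (0/1 for 2 states, 1..4 for pair states).
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @return For a 2x2 generator, a named 0/1 tip vector. For a 4x4
#'   generator, a 2-column 0/1 matrix (columns `A`, `B`) with tip row
#'   names.
#' @export
simulate_trait <- function(tree, Q, root = "stationary", seed = NULL) {
  validate_phylogeny(tree)
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  k <- nrow(Q)
  Q <- unname(as.matrix(Q))
  root_state <- if (is.character(root)) {
    prior <- if (root == "uniform") rep(1 / k, k)
             else as.numeric(stationary_distribution(Q))
    sample.int(k, 1L, prob = prior)
  } else if (length(root) == k) {
    sample.int(k, 1L, prob = root)
  } else {
    s <- if (k == 2L) as.integer(root) + 1L else as.integer(root)
    stopifnot(s >= 1L, s <= k)
    s
  }
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  n_tip <- length(tr$tip.label)
  states <- integer(max(tr$edge))
  states[n_tip + 1L] <- root_state
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    states[ch] <- sim_edge(states[p], Q, tr$edge.length[e])
  }
  tips <- states[seq_len(n_tip)]
  if (k == 2L) return(setNames(tips - 1L, tr$tip.label))
  # decode pair index 1..4 = (0,0),(0,1),(1,0),(1,1)
  a <- as.integer(tips >= 3L)
  b <- as.integer(tips %in% c(2L, 4L))
  matrix(c(a, b), ncol = 2L, dimnames = list(tr$tip.label, c("A", "B")))
}

#' Dependent-pair generator from base rates and a coupling factor
#'
#' Positive coupling multiplies each trait's gain rate by `kappa` when the
#' partner is present and divides its loss rate by `kappa` when the
#' partner is present; `kappa = 1` recovers the independent model.
#'
#' @param q01_a,q10_a,q01_b,q10_b Base gain/loss rates of the two traits.
#' @param kappa Coupling factor (>= 1 for positive association).
#' @return A 4x4 generator ([rate_matrix4()]).
#' @export
coupled_pair_rates <- function(q01_a, q10_a, q01_b, q10_b, kappa = 1) {
  stopifnot(kappa > 0)
  rate_matrix4(alpha1 = q01_a, alpha2 = q01_a * kappa,
               beta1 = q01_b, beta2 = q01_b * kappa,
               gamma1 = q10_a, gamma2 = q10_a / kappa,
               delta1 = q10_b, delta2 = q10_b / kappa)
}

#' Simulation configuration
#'
#' Defaults emulate the study scale the analysis assumes: 72 strains on a
#' Yule tree, 265 GCF and 99 MF traits, single-trait gain/loss ratio 0.016
#' (loss rate 1 per unit tree depth), 9 truly linked pairs with coupling
#' `kappa = 8`, and an MF false-negative (dropout) rate of 0.1 modelling
#' condition-dependent non-production.
#'
#' @param n_strains,n_gcf,n_mf Dataset dimensions.
#' @param tree_rate Yule birth rate.
#' @param q10 Loss rate per unit depth.
#' @param ratio Gain/loss rate ratio (`q01 = ratio * q10`).
#' @param n_linked_pairs Number of truly linked GCF-MF pairs.
#' @param kappa Coupling factor of linked pairs (>= 1).
#' @param linked_q01,linked_q10 Base rates of linked-pair traits before
#'   coupling; the defaults (0.3 / 1) make the traits informative enough
#'   that repeated gains and losses are observable on a 72-tip tree.
#' @param mf_fn_rate MF dropout probability in `[0, 1)`.
#' @param max_retries Resimulation budget per linked pair.
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_strains = 72L, n_gcf = 265L, n_mf = 99L,
                              tree_rate = 1, q10 = 1, ratio = 0.016,
                              n_linked_pairs = 9L, kappa = 8,
                              linked_q01 = 0.6, linked_q10 = 3,
                              mf_fn_rate = 0.1, max_retries = 200L,
                              seed = 1L) {
  stopifnot(n_strains >= 2L, q10 > 0, ratio > 0, kappa >= 1,
            mf_fn_rate >= 0, mf_fn_rate < 1, n_linked_pairs >= 0L,
            n_linked_pairs <= min(n_gcf, n_mf))
  structure(list(n_strains = as.integer(n_strains),
                 n_gcf = as.integer(n_gcf), n_mf = as.integer(n_mf),
                 tree_rate = tree_rate, q10 = q10, q01 = ratio * q10,
                 ratio = ratio, n_linked_pairs = as.integer(n_linked_pairs),
                 kappa = kappa, linked_q01 = linked_q01,
                 linked_q10 = linked_q10, mf_fn_rate = mf_fn_rate,
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Synthesize a full dataset with ground truth
#'
#' Simulates the tree, background GCF and MF traits (independent, at the
#' configured gain/loss ratio, root drawn from the stationary
#' distribution), and the truly linked pairs under the coupled dependent
#' model. Each linked pair is resimulated (bounded retries) until both
#' traits show at least 2 parsimony changes after MF dropout, so every
#' truth pair passes the eligibility filter by construction. Dropout is
#' applied to all MF columns after simulation.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_truth` list: `tree`, `gcf`, `mf` (trait matrices),
#'   `truth` (data frame pair_id / gcf_id / mf_id / kappa / retries),
#'   `config`.
#' @export
synthesize_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- simulate_tree(config$n_strains, config$tree_rate, config$seed)
  set.seed(as.integer((config$seed + 104729) %% 2147483647L))
  strains <- tree$tip.label
  Q1 <- rate_matrix2(config$q01, config$q10)
  gcf <- matrix(0L, length(strains), config$n_gcf,
                dimnames = list(strains, sprintf("GCF_%03d", seq_len(config$n_gcf))))
  mf <- matrix(0L, length(strains), config$n_mf,
               dimnames = list(strains, sprintf("MF_%03d", seq_len(config$n_mf))))
  nl <- config$n_linked_pairs
  drop_mf <- function(v) {
    hit <- v == 1L & runif(length(v)) < config$mf_fn_rate
    v[hit] <- 0L
    v
  }
  truth <- NULL
  if (nl > 0L) {
    Qp <- coupled_pair_rates(config$linked_q01, config$linked_q10,
                             config$linked_q01, config$linked_q10,
                             config$kappa)
    rows <- vector("list", nl)
    for (k in seq_len(nl)) {
      ok <- FALSE
      for (r in seq_len(config$max_retries)) {
        ab <- simulate_trait(tree, Qp, root = "stationary")
        a <- ab[strains, "A"]
        b <- drop_mf(ab[strains, "B"])
        if (parsimony_changes(tree, setNames(a, strains)) >= 2L &&
            parsimony_changes(tree, setNames(b, strains)) >= 2L) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop("retry budget exhausted for linked pair ", k,
             "; increase kappa or the linked-pair rates")
      gcf[, k] <- a
      mf[, k] <- b
      rows[[k]] <- data.frame(pair_id = sprintf("pair_%02d", k),
                              gcf_id = colnames(gcf)[k],
                              mf_id = colnames(mf)[k],
                              kappa = config$kappa, retries = r,
                              stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
  } else {
    truth <- data.frame(pair_id = character(0), gcf_id = character(0),
                        mf_id = character(0), kappa = numeric(0),
                        retries = integer(0), stringsAsFactors = FALSE)
  }
  for (j in seq_len(config$n_gcf)) {
    if (nl > 0L && j <= nl) next
    gcf[, j] <- simulate_trait(tree, Q1, root = "stationary")[strains]
  }
  for (j in seq_len(config$n_mf)) {
    if (nl > 0L && j <= nl) next
    mf[, j] <- drop_mf(simulate_trait(tree, Q1, root = "stationary")[strains])
  }
  structure(list(tree = tree, gcf = trait_matrix(gcf, "GCF"),
                 mf = trait_matrix(mf, "MF"), truth = truth,
                 config = config),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth: %d strains, %d GCFs, %d MFs, %d linked pairs>\n",
              length(x$tree$tip.label), ncol(x$gcf), ncol(x$mf),
              nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `tree.nwk`, `gcf_matrix.tsv`, `mf_matrix.tsv` and `truth.tsv` in
#' the dialects the package's readers consume.
#'
#' @param x A `synthetic_truth`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_synthetic_dataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             gcf = file.path(dir, "gcf_matrix.tsv"),
             mf = file.path(dir, "mf_matrix.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_newick(x$tree, paths["tree"])
  write_trait_matrix(x$gcf, paths["gcf"])
  write_trait_matrix(x$mf, paths["mf"])
  write.table(x$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Synthesize a BGC curation fixture with planted superclusters
#'
#' Builds toy gene tables in which some genomes carry fused superclusters
#' of 2-3 core-gene blocks, partner genomes carry the matching single-block
#' regions, and distractor genomes carry regions with unrelated domain
#' content. The expected outcome of supercluster splitting (which parents
#' split into how many children) is emitted as ground truth.
#'
#' Because the stand-in clustering distance caps the similarity of a
#' K-block fusion to a single-block region at Jaccard 1/K, grouping
#' regions for split detection needs a permissive raw cutoff; the fixture
#' records the cutoff (`raw_cutoff = 0.8`) its truth assumes.
#'
#' @param seed Integer seed.
#' @param n_planted Number of fused superclusters to plant (default 2).
#' @param n_distractors Number of unrelated singleton regions (default 3).
#' @return List: `regions` (named list of [bgc_region()]s), `expected`
#'   (data frame parent / n_children), `raw_cutoff`.
#' @export
synthesize_curation_fixture <- function(seed = 1L, n_planted = 2L,
                                        n_distractors = 3L) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  regions <- list()
  expected <- list()
  gid <- 0L
  mk_gene <- function(id, start, width, category, domains) {
    data.frame(gene_id = id, start = start, end = start + width - 1L,
               strand = "+", category = category,
               domains = paste(domains, collapse = "|"),
               stringsAsFactors = FALSE)
  }
  for (s in seq_len(n_planted)) {
    n_blocks <- sample(2:3, 1L)
    # block domain pools; block 1 is domain-rich so at least one partner
    # stays within reach of the fused region under the stand-in distance
    blocks <- lapply(seq_len(n_blocks), function(k) {
      nd <- if (k == 1L) 6L else sample(3:4, 1L)
      sprintf("SC%d_B%d_D%d", s, k, seq_len(nd))
    })
    # fused supercluster on genome A
    genes <- list(); pos <- 1L
    for (k in seq_len(n_blocks)) {
      doms <- blocks[[k]]
      ncore <- sample(2:3, 1L)
      split_doms <- split(doms, cut(seq_along(doms), ncore, labels = FALSE))
      for (ci in seq_len(ncore)) {
        gid <- gid + 1L
        genes[[length(genes) + 1L]] <-
          mk_gene(sprintf("g%04d", gid), pos, 900L, "core", split_doms[[ci]])
        pos <- pos + 1000L
      }
      if (k < n_blocks) {
        n_fill <- sample(1:3, 1L)
        for (f in seq_len(n_fill)) {
          gid <- gid + 1L
          genes[[length(genes) + 1L]] <-
            mk_gene(sprintf("g%04d", gid), pos, 400L, "other", character(0))
          pos <- pos + 500L
        }
      }
    }
    fused_id <- sprintf("SC%d_fused", s)
    regions[[fused_id]] <- bgc_region(fused_id, sprintf("A%d", s), "c1",
                                      do.call(rbind, genes), "pks")
    # one partner genome per block carrying just that block
    for (k in seq_len(n_blocks)) {
      doms <- blocks[[k]]
      ncore <- 2L
      split_doms <- split(doms, cut(seq_along(doms), ncore, labels = FALSE))
      pg <- list(); pos <- 1L
      for (ci in seq_len(ncore)) {
        gid <- gid + 1L
        pg[[length(pg) + 1L]] <-
          mk_gene(sprintf("g%04d", gid), pos, 900L, "core", split_doms[[ci]])
        pos <- pos + 1000L
      }
      pid <- sprintf("SC%d_part%d", s, k)
      regions[[pid]] <- bgc_region(pid, sprintf("P%d_%d", s, k), "c1",
                                   do.call(rbind, pg), "pks")
    }
    expected[[length(expected) + 1L]] <-
      data.frame(parent = fused_id, n_children = n_blocks,
                 stringsAsFactors = FALSE)
  }
  for (d in seq_len(n_distractors)) {
    ng <- sample(2:4, 1L)
    dg <- list(); pos <- 1L
    for (ci in seq_len(ng)) {
      gid <- gid + 1L
      dg[[length(dg) + 1L]] <-
        mk_gene(sprintf("g%04d", gid), pos, 800L,
                sample(c("core", "other", "transport"), 1L),
                sprintf("DIS%d_D%d", d, ci))
      pos <- pos + 900L
    }
    did <- sprintf("DIS%d", d)
    regions[[did]] <- bgc_region(did, sprintf("Z%d", d), "c1",
                                 do.call(rbind, dg), "nrps")
  }
  expected <- if (length(expected)) do.call(rbind, expected) else
    data.frame(parent = character(0), n_children = integer(0),
               stringsAsFactors = FALSE)
  list(regions = regions[order(names(regions))], expected = expected,
       raw_cutoff = 0.8)
}

#' Synthesize an MS feature table consistent with an MF matrix
#'
#' For round-trip testing of the MF presence caller: generates, per MF,
#' `n_features` features; in strains where the MF is present, a fraction
#' of features (at least the calling threshold, always including one
#' `[M+H]+` feature) is marked detected across `n_replicates` replicates;
#' absent strains get sub-threshold or adduct-less detections.
#'
#' @param mf A [trait_matrix()] of kind `"MF"`.
#' @param n_features Features per MF (default 40).
#' @param n_replicates Replicates per strain (default 3).
#' @param seed Integer seed.
#' @return A feature-record data frame ([read_feature_table()] layout).
#' @export
synthesize_feature_table <- function(mf, n_features = 40L,
                                     n_replicates = 3L, seed = 1L) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  rows <- list()
  adducts <- c("[M+H]+", "[M+Na]+", "[M+K]+")
  for (m in colnames(mf)) {
    feats <- sprintf("%s_f%03d", m, seq_len(n_features))
    fadd <- c("[M+H]+", sample(adducts, n_features - 1L, replace = TRUE))
    for (s in rownames(mf)) {
      present <- unclass(mf)[s, m] == 1L
      n_det <- if (present) max(ceiling(0.03 * n_features),
                                sample(ceiling(0.03 * n_features):
                                       ceiling(0.25 * n_features), 1L))
               else sample(0:max(0L, ceiling(0.03 * n_features) - 2L), 1L)
      det_idx <- if (present) {
        c(1L, sample(seq_len(n_features)[-1L], max(n_det - 1L, 0L)))
      } else if (n_det > 0L) {
        sample(which(fadd != "[M+H]+"), min(n_det, sum(fadd != "[M+H]+")))
      } else integer(0)
      for (i in det_idx) {
        det_reps <- sample(seq_len(n_replicates), sample(n_replicates, 1L))
        for (r in seq_len(n_replicates)) {
          rows[[length(rows) + 1L]] <-
            data.frame(feature_id = feats[i], mf_id = m, adduct = fadd[i],
                       strain_id = s, replicate_id = paste0("rep", r),
                       detected = as.integer(r %in% det_reps),
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(feature_id = character(0), mf_id = character(0),
                      adduct = character(0), strain_id = character(0),
                      replicate_id = character(0), detected = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
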