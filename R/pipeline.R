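#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order, writing every
#' artifact to `out_dir` and a `manifest.json` listing outputs with md5
#' checksums, parameters and seeds. Stages:
#'
#' * `simulate` — synthesize tree + matrices + truth
#'   ([synthesize_dataset()]); the truth table doubles as a known-pair
#'   catalog for `evaluate`/`permute`.
#' * `call_mfs` — MF presence matrix from a feature table
#'   ([call_mf_presence()]).
#' * `curate` — BGC curation and GCF clustering from a gene table
#'   ([curate_and_cluster()]).
#' * `associate` — phylogeny-aware screen ([associate_all()]).
#' * `chisq` — comparator screen ([chisq_screen()]).
#' * `evaluate` — known-pair evaluation of available screens
#'   ([evaluate_known_pairs()], [fold_reduction()]).
#' * `permute` — permutation control ([permutation_control()]).
#' * `rarefy` — GCF richness rarefaction ([incidence_rarefaction()]).
#'
#' Inputs not produced by an earlier stage are read from the paths in
#' `config$inputs`; a missing file is an error naming the path. No stage
#' mutates its inputs. Reruns with an identical config produce identical
#' checksums.
#'
#' @param config A named list (or path to a JSON file holding one) with
#'   elements `stages` (character vector), `out_dir`, `seed`, optional
#'   `alpha`, `rq_min`, `min_changes`, `cutoff`, `n_perm`, `mode`
#'   (`strict`/`prune`), `simulate` (arguments for [simulation_config()]),
#'   and `inputs` (paths: `tree`, `gcf_matrix`, `mf_matrix`,
#'   `feature_table`, `gene_table`, `known_pairs`).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$stages), !is.null(config$out_dir))
  defaults <- list(alpha = 0.01, rq_min = 0.65, min_changes = 2L,
                   cutoff = 0.4, n_perm = 20L, seed = 1L, mode = "strict")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  stopifnot(config$alpha > 0, config$alpha < 1,
            config$cutoff > 0, config$cutoff <= 1)
  known <- c("simulate", "call_mfs", "curate", "associate", "chisq",
             "evaluate", "permute", "rarefy")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (p in unlist(config$inputs))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  state <- new.env(parent = emptyenv())
  manifest <- list(parameters = config[setdiff(names(config), "inputs")],
                   inputs = config$inputs, outputs = list())
  emit <- function(name, path) {
    manifest$outputs[[name]] <<- list(path = path,
                                      md5 = unname(tools::md5sum(path)))
  }
  need_tree <- function() {
    if (is.null(state$tree)) state$tree <- read_newick(in_path("tree"))
    state$tree
  }
  in_path <- function(key) {
    p <- config$inputs[[key]]
    if (is.null(p)) stop("stage needs input '", key,
                         "' (not produced by an earlier stage)")
    p
  }
  need_matrix <- function(kind) {
    slot <- if (kind == "GCF") "gcf" else "mf"
    if (is.null(state[[slot]]))
      state[[slot]] <- read_trait_matrix(
        in_path(if (kind == "GCF") "gcf_matrix" else "mf_matrix"), kind)
    state[[slot]]
  }
  need_catalog <- function() {
    if (!is.null(state$truth))
      return(known_pair_catalog(data.frame(compound = state$truth$pair_id,
                                           gcf_id = state$truth$gcf_id,
                                           mf_id = state$truth$mf_id)))
    read_known_pairs(in_path("known_pairs"))
  }
  validated <- function() {
    v <- validate_dataset(need_tree(),
                          list(gcf = need_matrix("GCF"), mf = need_matrix("MF")),
                          mode = config$mode)
    state$tree <- v$tree; state$gcf <- v$matrices$gcf
    state$mf <- v$matrices$mf
    v
  }

  for (stage in config$stages) {
    message("[phylolink] stage: ", stage)
    if (stage == "simulate") {
      sim_args <- config$simulate
      if (is.null(sim_args)) sim_args <- list()
      sim_args$seed <- config$seed
      truthset <- do.call(simulation_config, sim_args)
      ds <- synthesize_dataset(truthset)
      paths <- write_synthetic_dataset(ds, config$out_dir)
      for (nm in names(paths)) emit(paste0("simulate_", nm), paths[[nm]])
      state$tree <- ds$tree; state$gcf <- ds$gcf; state$mf <- ds$mf
      state$truth <- ds$truth
    } else if (stage == "call_mfs") {
      feats <- read_feature_table(in_path("feature_table"))
      cat_ <- mf_catalog(feats)
      state$mf <- call_mf_presence(feats, cat_)
      p <- file.path(config$out_dir, "mf_matrix_called.tsv")
      write_trait_matrix(state$mf, p); emit("mf_matrix_called", p)
    } else if (stage == "curate") {
      regions <- read_gene_table(in_path("gene_table"))
      genomes <- sort(unique(vapply(regions, `[[`, character(1L),
                                    "genome_id")))
      cur <- curate_and_cluster(regions, genomes, cutoff = config$cutoff)
      state$gcf <- cur$matrix
      p1 <- file.path(config$out_dir, "gcf_matrix_curated.tsv")
      p2 <- file.path(config$out_dir, "split_log.tsv")
      write_trait_matrix(cur$matrix, p1)
      write.table(cur$split_log, p2, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit("gcf_matrix_curated", p1); emit("split_log", p2)
    } else if (stage == "associate") {
      v <- validated()
      state$phylo <- associate_all(state$gcf, state$mf, state$tree,
                                   alpha = config$alpha,
                                   rq_min = config$rq_min,
                                   min_changes = config$min_changes,
                                   seed = config$seed)
      p <- file.path(config$out_dir, "associations_phylo.tsv")
      write.table(state$phylo, p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit("associations_phylo", p)
    } else if (stage == "chisq") {
      validated()
      state$chisq <- chisq_screen(state$gcf, state$mf, alpha = config$alpha)
      p <- file.path(config$out_dir, "associations_chisq.tsv")
      write.table(state$chisq, p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      emit("associations_chisq", p)
    } else if (stage == "evaluate") {
      cat_ <- need_catalog()
      ev <- list()
      if (!is.null(state$phylo))
        ev$phylo <- evaluate_known_pairs(state$phylo, cat_)
      if (!is.null(state$chisq))
        ev$chisq <- evaluate_known_pairs(state$chisq, cat_)
      if (!length(ev)) stop("evaluate: no screen results available; run ",
                            "'associate' and/or 'chisq' first")
      out <- lapply(ev, function(e)
        list(per_compound = e$per_compound,
             correct_total = e$correct_total,
             false_positive_total = e$false_positive_total))
      if (!is.null(ev$phylo) && !is.null(ev$chisq))
        out$fold_reduction <- fold_reduction(ev$phylo, ev$chisq)
      p <- file.path(config$out_dir, "evaluation.json")
      jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
      emit("evaluation", p)
    } else if (stage == "permute") {
      validated()
      cat_ <- need_catalog()
      perms <- permutation_control(state$gcf, state$mf, state$tree, cat_,
                                   n_perm = config$n_perm,
                                   seed = config$seed,
                                   alpha = config$alpha,
                                   rq_min = config$rq_min,
                                   min_changes = config$min_changes)
      summ <- lapply(perms, function(pr) {
        r <- list(seed = pr$seed)
        for (m in c("phylo", "chisq"))
          if (!is.null(pr[[m]]))
            r[[m]] <- list(correct = pr[[m]]$correct_total,
                           false_positives = pr[[m]]$false_positive_total)
        r
      })
      p <- file.path(config$out_dir, "permutation_control.json")
      jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      emit("permutation_control", p)
    } else if (stage == "rarefy") {
      m <- if (!is.null(state$gcf)) state$gcf else need_matrix("GCF")
      curve <- incidence_rarefaction(m, extrapolate_to = 3L * nrow(m))
      p <- file.path(config$out_dir, "rarefaction.tsv")
      write_incidence_curve(curve, p)
      emit("rarefaction", p)
      manifest$rarefaction <- list(s_obs = curve$s_obs, chao2 = curve$chao2,
                                   q1 = curve$q1, q2 = curve$q2)
    }
  }
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
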