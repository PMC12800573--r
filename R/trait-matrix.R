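#' Construct a binary trait matrix
#'
#' A `trait_matrix` is an integer matrix of 0/1 values with strains as rows
#' and traits (GCFs or MFs) as columns, tagged with the trait kind.
#'
#' @param x A matrix (or object coercible to one) of 0/1 values with row
#'   names = strain ids and column names = trait ids.
#' @param kind `"GCF"` or `"MF"`.
#' @return A `trait_matrix` object.
#' @export
trait_matrix <- function(x, kind = c("GCF", "MF")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("trait matrix needs strain ids as row names")
  if (is.null(colnames(x)) && ncol(x) > 0)
    stop("trait matrix needs trait ids as column names")
  rownames(x) <- trimws(rownames(x))
  if (ncol(x) > 0) colnames(x) <- trimws(colnames(x))
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(x))
    stop("non-binary cell at strain '", rownames(x)[i[1L]], "', trait '",
         colnames(x)[i[2L]], "': value ", x[bad[1L]])
  }
  if (anyDuplicated(rownames(x)))
    stop("duplicate strain ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (ncol(x) > 0 && anyDuplicated(colnames(x)))
    stop("duplicate trait ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  storage.mode(x) <- "integer"
  structure(x, class = c("trait_matrix", class(matrix())), kind = kind)
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix kind=%s: %d strains x %d traits, %d presences>\n",
              attr(x, "kind"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Trait kind of a trait matrix
#' @param x A `trait_matrix`.
#' @return `"GCF"` or `"MF"`.
#' @export
trait_kind <- function(x) attr(x, "kind")

#' Read a trait presence/absence matrix from TSV
#'
#' Expects a UTF-8 tab-separated table whose first column holds strain ids
#' and whose remaining columns, named in the header, hold 0/1 presence
#' calls. Non-binary cells and duplicate strain ids are hard errors naming
#' the offending cell or id.
#'
#' @param path Path to the TSV file.
#' @param kind Trait kind tag, `"GCF"` or `"MF"`.
#' @return A [trait_matrix()].
#' @export
read_trait_matrix <- function(path, kind = c("GCF", "MF")) {
  kind <- match.arg(kind)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 1L) stop("empty trait table: ", path)
  strains <- trimws(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  m <- matrix(0L, nrow(df), ncol(vals),
              dimnames = list(strains, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- trimws(vals[[j]])
    ok <- v %in% c("0", "1")
    if (!all(ok)) {
      i <- which(!ok)[1L]
      stop("non-binary cell in ", path, " at strain '", strains[i],
           "', trait '", colnames(vals)[j], "': '", v[i], "'")
    }
    m[, j] <- as.integer(v)
  }
  trait_matrix(m, kind)
}

#' Write a trait matrix to TSV
#' @param x A `trait_matrix`.
#' @param path Output path.
#' @param id_col Name for the strain-id column (default `"strain_id"`).
#' @return `path`, invisibly.
#' @export
write_trait_matrix <- function(x, path, id_col = "strain_id") {
  df <- data.frame(rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check strain concordance between a tree and trait matrices
#'
#' Compares the tree's tip set against the strain sets of one or more trait
#' matrices. In `"strict"` mode any mismatch is an error enumerating the
#' offending ids; in `"prune"` mode the tree and all matrices are reduced
#' symmetrically to the common strain intersection and the removals are
#' recorded in the report.
#'
#' @param tree A `phylo` object.
#' @param matrices A list of [trait_matrix()] objects (named if possible).
#' @param mode `"strict"` or `"prune"`.
#' @return A list with elements `tree`, `matrices` and `report`. The report
#'   is a JSON-serializable list with, per matrix, the ids missing from the
#'   tree and from the matrix, plus any pruned ids.
#' @export
validate_dataset <- function(tree, matrices, mode = c("strict", "prune")) {
  mode <- match.arg(mode)
  validate_phylogeny(tree)
  if (inherits(matrices, "trait_matrix")) matrices <- list(matrices)
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    names(matrices) <- paste0("matrix", seq_along(matrices))
  tips <- tree$tip.label
  report <- list(mode = mode, matrices = list())
  shared <- tips
  mismatch <- FALSE
  for (nm in names(matrices)) {
    strains <- rownames(matrices[[nm]])
    extra <- setdiff(strains, tips)
    missing <- setdiff(tips, strains)
    report$matrices[[nm]] <- list(missing_from_tree = extra,
                                  missing_from_matrix = missing)
    if (length(extra) || length(missing)) mismatch <- TRUE
    shared <- intersect(shared, strains)
  }
  if (mode == "strict") {
    if (mismatch) {
      det <- vapply(names(matrices), function(nm) {
        r <- report$matrices[[nm]]
        sprintf("%s: missing_from_tree=[%s] missing_from_matrix=[%s]", nm,
                paste(r$missing_from_tree, collapse = ","),
                paste(r$missing_from_matrix, collapse = ","))
      }, character(1L))
      stop("strain sets of tree and matrices differ:\n",
           paste(det, collapse = "\n"))
    }
    return(list(tree = tree, matrices = matrices, report = report))
  }
  # prune mode: symmetric reduction to the intersection
  if (length(shared) < 2L)
    stop("fewer than 2 strains shared between tree and matrices")
  pruned_tips <- setdiff(tips, shared)
  if (length(pruned_tips)) tree <- ape::keep.tip(tree, shared)
  matrices <- lapply(matrices, function(m) {
    kept <- trait_matrix(unclass(m)[tree$tip.label, , drop = FALSE],
                         trait_kind(m))
    kept
  })
  report$pruned <- list(from_tree = pruned_tips,
                        shared_strains = length(shared))
  list(tree = tree, matrices = matrices, report = report)
}

#' Catalog of known compound-to-GCF/MF pairs
#'
#' @param df A data frame with columns `compound`, `gcf_id`, `mf_id`.
#' @return A `known_pair_catalog` (validated data frame).
#' @export
known_pair_catalog <- function(df) {
  need <- c("compound", "gcf_id", "mf_id")
  if (!all(need %in% names(df)))
    stop("catalog needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  for (j in need) df[[j]] <- trimws(as.character(df[[j]]))
  if (anyDuplicated(df$compound))
    stop("duplicate compound names: ",
         paste(unique(df$compound[duplicated(df$compound)]), collapse = ", "))
  structure(df, class = c("known_pair_catalog", "data.frame"))
}

#' Read a known-pair catalog from TSV
#' @param path TSV with columns compound, gcf_id, mf_id.
#' @return A [known_pair_catalog()].
#' @export
read_known_pairs <- function(path) {
  known_pair_catalog(read.delim(path, stringsAsFactors = FALSE))
}
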