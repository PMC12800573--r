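#' Read a rooted phylogeny from a newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream likelihood and parsimony machinery relies on: a single tree,
#' branch lengths on every edge, all lengths finite and non-negative,
#' unique non-empty tip labels, and at least two tips. Multifurcations are
#' preserved; internal node labels are treated as support values and
#' ignored. Tip labels are trimmed of surrounding whitespace.
#'
#' @param path Path to a file containing exactly one newick tree.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_parens(txt)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("malformed newick in ", path)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected exactly one tree, found ", length(tree))
    tree <- tree[[1L]]
  }
  tree$tip.label <- trimws(tree$tip.label)
  validate_phylogeny(tree)
  tree
}

# Balanced-parenthesis pre-check so parse failures name a character offset,
# which ape's parser does not report.
check_newick_parens <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed newick: unmatched ')' at character offset ", i)
    }
  }
  if (depth != 0L)
    stop("malformed newick: ", depth, " unclosed '(' at character offset ",
         nchar(txt))
  invisible(TRUE)
}

#' Validate phylogeny invariants
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  n <- length(tree$tip.label)
  if (n < 2L) stop("tree must have >= 2 tips, found ", n)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (any(!nzchar(tree$tip.label))) stop("empty tip label")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; branch lengths are required")
  if (any(!is.finite(tree$edge.length)))
    stop("non-finite branch length")
  if (any(tree$edge.length < 0))
    stop("negative branch length: min = ", min(tree$edge.length))
  invisible(tree)
}

#' Write a phylogeny to a newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Root-to-tip depths of all tips
#' @param tree A `phylo` object.
#' @return Named numeric vector of tip depths.
#' @keywords internal
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  setNames(d[seq_along(tree$tip.label)], tree$tip.label)
}

#' Rescale a tree to unit mean root-to-tip depth
#'
#' Rates in this package are expressed per unit branch length; fitting on a
#' tree rescaled so that the mean root-to-tip path is 1 makes rate bounds
#' and defaults comparable across datasets. Rate ratios are invariant to
#' this scaling.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return The rescaled tree; the factor applied is stored in
#'   `attr(tree, "depth_scale")`.
#' @export
rescale_tree_depth <- function(tree) {
  md <- mean(tip_depths(tree))
  if (!is.finite(md) || md <= 0)
    stop("cannot rescale: mean root-to-tip depth is ", md)
  tree$edge.length <- tree$edge.length / md
  attr(tree, "depth_scale") <- md
  tree
}
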