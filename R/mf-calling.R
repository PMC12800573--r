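#' Read an MS feature detection table
#'
#' Tab-separated with columns `feature_id`, `mf_id`, `adduct`, `strain_id`,
#' `replicate_id`, `detected` (0/1). One row per feature x strain x
#' replicate observation.
#'
#' @param path Path to the TSV.
#' @return A data frame of feature records.
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("feature_id", "mf_id", "adduct", "strain_id", "replicate_id",
            "detected")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("feature table missing columns: ",
                         paste(miss, collapse = ", "))
  df$detected <- as.integer(df$detected)
  if (any(!df$detected %in% c(0L, 1L)))
    stop("feature table column 'detected' must be 0/1")
  for (j in c("feature_id", "mf_id", "adduct", "strain_id"))
    df[[j]] <- trimws(as.character(df[[j]]))
  df
}

#' Build an MF catalog from feature records
#'
#' Maps each metabolite family (MF) to its member feature ids and carries
#' the presence thresholds applied by [call_mf_presence()].
#'
#' @param features A feature-record data frame (see [read_feature_table()]).
#' @param fraction Minimum fraction of an MF's features that must be
#'   detected in a strain (default 0.03, i.e. "at least 3%").
#' @param min_mh Minimum number of detected `[M+H]+` features (default 1).
#' @return An `mf_catalog` list.
#' @export
mf_catalog <- function(features, fraction = 0.03, min_mh = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  members <- tapply(features$feature_id, features$mf_id,
                    function(x) sort(unique(x)), simplify = FALSE)
  sizes <- vapply(members, length, integer(1L))
  if (any(sizes == 0L)) stop("MF with zero features: ",
                             paste(names(members)[sizes == 0L], collapse = ", "))
  structure(list(members = members, fraction = fraction, min_mh = min_mh),
            class = "mf_catalog")
}

# Canonicalize adduct labels: strip all whitespace so "[M + H]+" dialects
# match the canonical "[M+H]+"; extra synonyms can be supplied as a map.
canon_adduct <- function(x, synonyms = NULL) {
  x <- gsub("[[:space:]]", "", x)
  if (!is.null(synonyms)) {
    hit <- x %in% names(synonyms)
    x[hit] <- unname(synonyms[x[hit]])
  }
  x
}

#' Call MF presence per strain from feature detections
#'
#' A metabolite family is called present in a strain iff (a) the fraction
#' of the MF's features detected in that strain is at least `fraction`
#' (default 3%), and (b) at least one detected feature of the MF carries
#' the protonated-molecule adduct `[M+H]+` in that strain. A feature counts
#' as detected in a strain when it is detected in at least one replicate
#' (configurable to a majority rule). The fraction comparison is done in
#' integer arithmetic so that boundary cases (e.g. exactly 3%) are exact.
#'
#' @param features Feature-record data frame; every `mf_id` must exist in
#'   the catalog.
#' @param catalog An [mf_catalog()].
#' @param strains Optional character vector of strains to report (rows);
#'   strains with no detections get all-zero rows. Defaults to the strains
#'   present in the feature table.
#' @param replicate_rule `"any"` (default) or `"majority"`.
#' @param adduct_synonyms Optional named character vector mapping adduct
#'   dialect spellings to canonical ones.
#' @param count_distinct_features Count distinct feature ids (default TRUE)
#'   rather than feature x adduct combinations in the fraction rule.
#' @return A [trait_matrix()] of kind `"MF"`.
#' @export
call_mf_presence <- function(features, catalog, strains = NULL,
                             replicate_rule = c("any", "majority"),
                             adduct_synonyms = NULL,
                             count_distinct_features = TRUE) {
  replicate_rule <- match.arg(replicate_rule)
  stopifnot(inherits(catalog, "mf_catalog"))
  unknown <- setdiff(unique(features$mf_id), names(catalog$members))
  if (length(unknown))
    stop("features reference unknown MFs: ", paste(unknown, collapse = ", "))
  if (is.null(strains)) strains <- sort(unique(features$strain_id))
  mfs <- names(catalog$members)
  features$adduct <- canon_adduct(features$adduct, adduct_synonyms)

  # collapse replicates -> rows detected per feature x adduct x strain
  grp <- c("feature_id", "adduct", "strain_id", "mf_id")
  if (replicate_rule == "any") {
    det <- unique(features[features$detected == 1L, grp, drop = FALSE])
  } else {
    agg <- aggregate(cbind(hits = features$detected,
                           reps = rep(1L, nrow(features))),
                     by = features[grp], FUN = sum)
    det <- agg[agg$hits * 2L > agg$reps, grp, drop = FALSE]
  }

  m <- matrix(0L, length(strains), length(mfs),
              dimnames = list(strains, mfs))
  mh <- "[M+H]+"
  for (mf in mfs) {
    n_feat <- length(catalog$members[[mf]])
    sub <- det[det$mf_id == mf & det$strain_id %in% strains, , drop = FALSE]
    if (!nrow(sub)) next
    for (s in unique(sub$strain_id)) {
      ss <- sub[sub$strain_id == s, , drop = FALSE]
      n_det <- if (count_distinct_features) length(unique(ss$feature_id))
               else nrow(ss)
      # integer comparison: n_det / n_feat >= fraction, exact at boundary
      frac_ok <- n_det * 10000L >= as.integer(round(catalog$fraction * 10000)) * n_feat
      mh_ok <- sum(ss$adduct == mh) >= catalog$min_mh
      if (frac_ok && mh_ok) m[s, mf] <- 1L
    }
  }
  trait_matrix(m, "MF")
}
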