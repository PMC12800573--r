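#' Construct a BGC region
#'
#' A biosynthetic gene cluster (BGC) region is an ordered run of genes on a
#' genome interval, as predicted by cluster-detection tools. Genes carry a
#' functional category (`core`, `additional`, `transport`, `regulatory`,
#' `other`) and an ordered list of protein-domain family labels.
#'
#' @param region_id,genome_id,contig_id Identifiers.
#' @param genes Data frame with columns `gene_id`, `start`, `end`, `strand`,
#'   `category`, `domains` (family labels joined with `"|"`, may be empty).
#'   Coordinates are 1-based inclusive.
#' @param product_class Free-text product class tag.
#' @return A `bgc_region` object.
#' @export
bgc_region <- function(region_id, genome_id, contig_id, genes,
                       product_class = "unknown") {
  need <- c("gene_id", "start", "end", "strand", "category", "domains")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(genes) < 1L) stop("region ", region_id, " has no genes")
  genes <- as.data.frame(genes)[need]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start > genes$end))
    stop("region ", region_id, ": gene with start > end")
  vocab <- c("core", "additional", "transport", "regulatory", "other")
  bad <- setdiff(unique(genes$category), vocab)
  if (length(bad))
    stop("region ", region_id, ": unknown gene category: ",
         paste(bad, collapse = ", "))
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(region_id = region_id, genome_id = genome_id,
                 contig_id = contig_id, start = min(genes$start),
                 end = max(genes$end), product_class = product_class,
                 genes = genes),
            class = "bgc_region")
}

#' @export
print.bgc_region <- function(x, ...) {
  cat(sprintf("<bgc_region %s (%s): %d genes, %d core, %d-%d bp>\n",
              x$region_id, x$genome_id, nrow(x$genes),
              sum(x$genes$category == "core"), x$start, x$end))
  invisible(x)
}

# per-gene domain label vectors, in gene order
gene_domain_list <- function(region) {
  lapply(strsplit(region$genes$domains, "|", fixed = TRUE),
         function(d) d[nzchar(d)])
}

region_domain_set <- function(region, core_only = FALSE) {
  g <- region$genes
  dl <- gene_domain_list(region)
  if (core_only) dl <- dl[g$category == "core"]
  unique(unlist(dl))
}

# ordered domain sequence (genes in order, domains within gene in order)
region_domain_seq <- function(region) unlist(gene_domain_list(region))

#' Read a BGC gene table from TSV
#'
#' Expects columns `genome_id`, `contig_id`, `region_id`, `gene_id`,
#' `start`, `end`, `strand`, `category`, `domains` and optionally
#' `product_class`. Returns a named list of [bgc_region()] objects.
#'
#' @param path Path to the TSV.
#' @return Named list of `bgc_region`s (names = region ids).
#' @export
read_gene_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  regions_from_gene_table(df)
}

#' Assemble regions from a long gene table
#' @param df Gene table data frame (see [read_gene_table()]).
#' @return Named list of `bgc_region`s.
#' @export
regions_from_gene_table <- function(df) {
  need <- c("genome_id", "contig_id", "region_id", "gene_id", "start", "end",
            "strand", "category", "domains")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"product_class" %in% names(df)) df$product_class <- "unknown"
  out <- lapply(split(df, df$region_id), function(sub) {
    bgc_region(sub$region_id[1L], sub$genome_id[1L], sub$contig_id[1L],
               sub[, c("gene_id", "start", "end", "strand", "category",
                       "domains")],
               product_class = sub$product_class[1L])
  })
  out[order(names(out))]
}

#' Flatten regions back to a long gene table
#' @param regions Named list of `bgc_region`s.
#' @return Data frame in the [read_gene_table()] layout.
#' @export
gene_table_from_regions <- function(regions) {
  do.call(rbind, lapply(regions, function(r) {
    data.frame(genome_id = r$genome_id, contig_id = r$contig_id,
               region_id = r$region_id, r$genes,
               product_class = r$product_class,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Write regions as a gene table TSV
#' @param regions Named list of `bgc_region`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(regions, path) {
  write.table(gene_table_from_regions(regions), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Find matched collinear gene blocks between two regions
#'
#' A gene of region `a` is matched when it shares at least one domain
#' family with some gene of region `b`. Maximal runs of matched `a`-genes
#' are merged across gaps of at most `gap_genes` unmatched genes. Each
#' block records the matched gene index ranges on both regions and its
#' anchor — the set of domain families shared between core genes on the
#' two sides; blocks without a core anchor are dropped (they cannot carry
#' evidence for splitting).
#'
#' @param a,b `bgc_region` objects.
#' @param gap_genes Maximum number of unmatched genes bridged within a
#'   block (default 2).
#' @return List of blocks, each `list(a_range, b_range, anchor)`, in
#'   region-`a` order; empty list if nothing matches.
#' @export
match_blocks <- function(a, b, gap_genes = 2L) {
  da <- gene_domain_list(a)
  db <- gene_domain_list(b)
  # per a-gene: indices of b-genes sharing >= 1 domain family
  hits <- lapply(da, function(d) {
    if (!length(d)) return(integer(0))
    which(vapply(db, function(e) any(d %in% e), logical(1L)))
  })
  matched <- which(lengths(hits) > 0L)
  if (!length(matched)) return(list())
  # merge runs across gaps of <= gap_genes unmatched genes
  runs <- split(matched, cumsum(c(1L, diff(matched) > gap_genes + 1L)))
  out <- list()
  for (run in runs) {
    bidx <- sort(unique(unlist(hits[run])))
    a_core <- run[a$genes$category[run] == "core"]
    b_rng <- range(bidx)
    b_core <- intersect(seq(b_rng[1L], b_rng[2L]),
                        which(b$genes$category == "core"))
    anchor <- intersect(unique(unlist(da[a_core])),
                        unique(unlist(db[b_core])))
    if (!length(anchor)) next
    out[[length(out) + 1L]] <- list(a_range = range(run), b_range = b_rng,
                                    anchor = sort(anchor))
  }
  out
}

#' Reduce a region to its core biosynthetic genes
#'
#' Drops all genes whose category is not `core`, preserving order, and
#' shrinks the region interval to the retained span. Regions with no core
#' gene cannot be meaningfully clustered on core content and are returned
#' as `NULL` (callers log and exclude them). Idempotent.
#'
#' @param region A `bgc_region`.
#' @return A `bgc_region` containing only core genes, or `NULL` if the
#'   region has none.
#' @export
reduce_to_core <- function(region) {
  keep <- region$genes$category == "core"
  if (!any(keep)) return(NULL)
  bgc_region(region$region_id, region$genome_id, region$contig_id,
             region$genes[keep, , drop = FALSE],
             product_class = region$product_class)
}

#' Reduce a region set to core genes, logging exclusions
#' @param regions Named list of `bgc_region`s.
#' @return `list(regions = <core-reduced list>, excluded = <region ids>)`.
#' @export
reduce_regions_to_core <- function(regions) {
  red <- lapply(regions, reduce_to_core)
  excluded <- names(regions)[vapply(red, is.null, logical(1L))]
  list(regions = red[!vapply(red, is.null, logical(1L))], excluded = excluded)
}

# Jaccard with the convention J(empty, empty) = 1
jaccard <- function(x, y) {
  u <- union(x, y)
  if (!length(u)) return(1)
  length(intersect(x, y)) / length(u)
}

region_bigrams <- function(region) {
  s <- region_domain_seq(region)
  if (length(s) < 2L) return(character(0))
  unique(paste(s[-length(s)], s[-1L], sep = ">"))
}

#' Cluster BGC regions into gene cluster families
#'
#' Simplified domain-content clustering: the pairwise distance between two
#' regions is `1 - (w_j * Jaccard(domain sets) + w_a * Jaccard(domain
#' bigram sets))`, and regions connected by edges with distance at most
#' `cutoff` are joined into one GCF (single-linkage components). This is a
#' deliberately simple stand-in for external BGC-family clustering tools
#' (BiG-SCAPE-like), declared as such; it shares their qualitative
#' behaviour (identical regions at distance 0, disjoint domain content at
#' distance 1, monotone family counts in the cutoff) without reproducing
#' their alignment machinery. Bigram sets capture domain adjacency; when
#' both regions have fewer than two domains the adjacency term falls back
#' to 1 for identical domain sets and 0 otherwise.
#'
#' @param regions Named list of `bgc_region`s.
#' @param cutoff Distance cutoff joining regions into a family
#'   (default 0.4).
#' @param w_j,w_a Weights of the domain-set and adjacency terms
#'   (defaults 0.7 / 0.3; must sum to 1).
#' @return List of `gcf` objects: `list(gcf_id, members, core_domains)`,
#'   ids derived from the lexicographically smallest member region id.
#' @export
cluster_gcfs <- function(regions, cutoff = 0.4, w_j = 0.7, w_a = 0.3) {
  if (!length(regions)) stop("no regions to cluster")
  if (abs(w_j + w_a - 1) > 1e-9) stop("w_j + w_a must equal 1")
  ids <- sort(unname(vapply(regions, `[[`, character(1L), "region_id")))
  regions <- regions[ids]
  n <- length(regions)
  dsets <- lapply(regions, region_domain_set)
  bsets <- lapply(regions, region_bigrams)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(n - 1L, 0L))) for (j in seq(i + 1L, n)) {
    J <- jaccard(dsets[[i]], dsets[[j]])
    A <- if (!length(bsets[[i]]) && !length(bsets[[j]])) {
      as.numeric(setequal(dsets[[i]], dsets[[j]]))
    } else jaccard(bsets[[i]], bsets[[j]])
    d <- 1 - (w_j * J + w_a * A)
    if (d <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  out <- lapply(split(seq_len(n), roots), function(idx) {
    members <- ids[idx]
    core_dom <- sort(unlist(lapply(regions[members], region_domain_set,
                                   core_only = TRUE)))
    list(gcf_id = paste0("GCF_", members[1L]), members = members,
         core_domains = core_dom)
  })
  names(out) <- vapply(out, `[[`, character(1L), "gcf_id")
  out[order(names(out))]
}

#' Split superclusters using cross-strain evidence
#'
#' Detection tools can fuse several adjacent clusters into one over-long
#' "supercluster" region. Within each GCF, a member region is split when
#' its core genes partition into two or more groups such that (i) each
#' group is anchored by at least one core gene, (ii) at least one shorter
#' region from another genome in the same family matches exactly one group
#' (cross-strain evidence), and (iii) every cut falls in a gene gap
#' containing no core genes. Children keep their group's core genes plus
#' the interleaved non-core genes up to the cut (placed at the midpoint of
#' the non-core run between groups); genes are conserved exactly.
#'
#' @param gcfs GCF list from [cluster_gcfs()] computed on the raw regions.
#' @param regions Named list of all `bgc_region`s.
#' @param gap_genes Gap tolerance forwarded to [match_blocks()].
#' @return `list(regions = <revised named list>, split_log = <data frame
#'   parent / child / evidence_regions / cut_bp>)`.
#' @export
split_superclusters <- function(gcfs, regions, gap_genes = 2L) {
  log_rows <- list()
  out <- regions
  for (gcf in gcfs) {
    if (length(gcf$members) < 2L) next
    for (rid in gcf$members) {
      R <- regions[[rid]]
      core_pos <- which(R$genes$category == "core")
      if (length(core_pos) < 2L) next
      partners <- Filter(function(S) {
        S$genome_id != R$genome_id && nrow(S$genes) < nrow(R$genes)
      }, regions[setdiff(gcf$members, rid)])
      if (!length(partners)) next
      # core-rank coverage per partner; only contiguous proper subsets vote
      covers <- list()
      for (S in partners) {
        blocks <- match_blocks(R, S, gap_genes)
        if (!length(blocks)) next
        covered <- unique(unlist(lapply(blocks, function(b)
          seq(b$a_range[1L], b$a_range[2L]))))
        ranks <- which(core_pos %in% covered)
        if (!length(ranks) || length(ranks) == length(core_pos)) next
        if (any(diff(ranks) != 1L)) next
        covers[[S$region_id]] <- ranks
      }
      if (!length(covers)) next
      # cut between core ranks r and r+1 when some partner's coverage ends
      # at r or starts at r+1
      ncore <- length(core_pos)
      cut_after <- rep(FALSE, ncore - 1L)
      for (ranks in covers) {
        hi <- max(ranks); lo <- min(ranks)
        if (hi < ncore) cut_after[hi] <- TRUE
        if (lo > 1L) cut_after[lo - 1L] <- TRUE
      }
      if (!any(cut_after)) next
      grp <- cumsum(c(1L, as.integer(cut_after)))  # group of each core rank
      groups <- split(seq_len(ncore), grp)
      # cross-strain evidence: some partner matches exactly one group
      exact <- names(covers)[vapply(covers, function(r)
        any(vapply(groups, function(g) identical(as.integer(g),
                                                 as.integer(r)), logical(1L))),
        logical(1L))]
      if (!length(exact)) next
      # child gene spans: cut at the midpoint of each inter-group non-core run
      ngene <- nrow(R$genes)
      starts <- integer(length(groups)); ends <- integer(length(groups))
      starts[1L] <- 1L; ends[length(groups)] <- ngene
      for (k in seq_len(length(groups) - 1L)) {
        left_core <- core_pos[max(groups[[k]])]
        right_core <- core_pos[min(groups[[k + 1L]])]
        between <- if (right_core - left_core >= 2L)
          seq(left_core + 1L, right_core - 1L) else integer(0)
        stopifnot(all(R$genes$category[between] != "core"))
        take_left <- floor(length(between) / 2)
        ends[k] <- left_core + take_left
        starts[k + 1L] <- ends[k] + 1L
      }
      children <- vector("list", length(groups))
      for (k in seq_along(groups)) {
        cid <- sprintf("%s_s%d", rid, k)
        children[[k]] <- bgc_region(cid, R$genome_id, R$contig_id,
                                    R$genes[starts[k]:ends[k], , drop = FALSE],
                                    product_class = R$product_class)
        cut_bp <- if (k < length(groups))
          R$genes$end[ends[k]] else NA_integer_
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(parent = rid, child = cid,
                     evidence_regions = paste(exact, collapse = ","),
                     cut_bp = cut_bp, stringsAsFactors = FALSE)
      }
      out[[rid]] <- NULL
      for (ch in children) out[[ch$region_id]] <- ch
    }
  }
  split_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(parent = character(0), child = character(0),
               evidence_regions = character(0), cut_bp = integer(0),
               stringsAsFactors = FALSE)
  list(regions = out[order(names(out))], split_log = split_log)
}

#' GCF presence/absence matrix over strains
#'
#' @param gcfs GCF list from [cluster_gcfs()].
#' @param regions Named list of `bgc_region`s resolving the members.
#' @param genomes Character vector of strain ids (matrix rows).
#' @return A [trait_matrix()] of kind `"GCF"`; entry 1 iff the strain
#'   contributes at least one member region to the family.
#' @export
gcf_presence_matrix <- function(gcfs, regions, genomes) {
  m <- matrix(0L, length(genomes), length(gcfs),
              dimnames = list(genomes, names(gcfs)))
  for (gcf in gcfs) {
    for (rid in gcf$members) {
      g <- regions[[rid]]$genome_id
      if (is.null(g)) stop("GCF member region not found: ", rid)
      if (!g %in% genomes) stop("unknown genome id: ", g)
      m[g, gcf$gcf_id] <- 1L
    }
  }
  trait_matrix(m, "GCF")
}

#' Full BGC curation pipeline
#'
#' Raw regions are clustered, superclusters split on cross-strain
#' evidence, regions reduced to core genes (no-core regions excluded and
#' logged), and the core regions re-clustered into the final GCFs.
#'
#' @param regions Named list of raw `bgc_region`s.
#' @param genomes Strain ids for the presence matrix.
#' @param cutoff Clustering distance cutoff (default 0.4).
#' @param gap_genes Gap tolerance for block matching (default 2).
#' @return List with `gcfs`, `matrix` (GCF [trait_matrix()]), `split_log`,
#'   `excluded_no_core`, and the curated `regions`.
#' @export
curate_and_cluster <- function(regions, genomes, cutoff = 0.4,
                               gap_genes = 2L) {
  raw_gcfs <- cluster_gcfs(regions, cutoff = cutoff)
  sp <- split_superclusters(raw_gcfs, regions, gap_genes = gap_genes)
  red <- reduce_regions_to_core(sp$regions)
  gcfs <- cluster_gcfs(red$regions, cutoff = cutoff)
  mat <- gcf_presence_matrix(gcfs, red$regions, genomes)
  list(gcfs = gcfs, matrix = mat, split_log = sp$split_log,
       excluded_no_core = red$excluded, regions = red$regions)
}
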