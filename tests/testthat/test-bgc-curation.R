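# compact region builder: spec = list(list(category, domains), ...)
mk_region <- function(id, genome, spec, product = "pks") {
  genes <- do.call(rbind, lapply(seq_along(spec), function(i) {
    data.frame(gene_id = sprintf("%s_g%d", id, i),
               start = (i - 1L) * 1000L + 1L, end = (i - 1L) * 1000L + 900L,
               strand = "+", category = spec[[i]][[1L]],
               domains = paste(spec[[i]][[2L]], collapse = "|"),
               stringsAsFactors = FALSE)
  }))
  bgc_region(id, genome, "c1", genes, product)
}

test_that("match_blocks finds full, partial and empty overlaps", {
  a <- mk_region("rA", "gA", list(list("core", "X"), list("other", character(0)),
                                  list("core", "Y")))
  b_full <- mk_region("rB", "gB", list(list("core", "X"),
                                       list("other", character(0)),
                                       list("core", "Y")))
  blocks <- match_blocks(a, b_full)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1L]]$a_range, c(1L, 3L))
  expect_setequal(blocks[[1L]]$anchor, c("X", "Y"))

  b_disjoint <- mk_region("rC", "gC", list(list("core", "Z")))
  expect_length(match_blocks(a, b_disjoint), 0L)

  # a = [X-core, filler, Y-core], b = [X-core] -> one block covering X only
  b_x <- mk_region("rD", "gD", list(list("core", "X")))
  blocks <- match_blocks(a, b_x)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1L]]$a_range, c(1L, 1L))
  expect_equal(blocks[[1L]]$anchor, "X")
})

test_that("runs split only across gaps wider than gap_genes", {
  spec_a <- list(list("core", "X"), list("other", character(0)),
                 list("other", character(0)), list("other", character(0)),
                 list("core", "Y"))
  a <- mk_region("rA", "gA", spec_a)
  b <- mk_region("rB", "gB", list(list("core", "X"), list("core", "Y")))
  expect_length(match_blocks(a, b, gap_genes = 2L), 2L)
  expect_length(match_blocks(a, b, gap_genes = 3L), 1L)
})

test_that("reduce_to_core keeps core genes, drops coreless regions", {
  r <- mk_region("r1", "g1", list(list("core", "X"), list("other", "O"),
                                  list("core", "Y"), list("transport", "T"),
                                  list("regulatory", "R")))
  red <- reduce_to_core(r)
  expect_equal(nrow(red$genes), 2L)
  expect_true(all(red$genes$category == "core"))
  expect_equal(red$start, min(red$genes$start))
  # idempotence
  expect_identical(reduce_to_core(red), red)

  no_core <- mk_region("r2", "g1", list(list("other", "O")))
  expect_null(reduce_to_core(no_core))
  rr <- reduce_regions_to_core(list(r1 = r, r2 = no_core))
  expect_equal(rr$excluded, "r2")
})

test_that("identical regions cluster together, disjoint ones apart", {
  r1 <- mk_region("r1", "g1", list(list("core", c("X", "X2")),
                                   list("core", "Y")))
  r2 <- mk_region("r2", "g2", list(list("core", c("X", "X2")),
                                   list("core", "Y")))
  r3 <- mk_region("r3", "g3", list(list("core", "Z")))
  gcfs <- cluster_gcfs(list(r1 = r1, r2 = r2, r3 = r3), cutoff = 0.4)
  expect_length(gcfs, 2L)
  expect_setequal(gcfs[["GCF_r1"]]$members, c("r1", "r2"))
  expect_equal(gcfs[["GCF_r3"]]$members, "r3")
})

test_that("raising the cutoff never increases the number of GCFs", {
  set.seed(21)
  pool <- LETTERS[1:8]
  regions <- lapply(1:12, function(i) {
    doms <- sample(pool, sample(2:4, 1L))
    mk_region(sprintf("r%02d", i), sprintf("g%d", i),
              lapply(doms, function(d) list("core", d)))
  })
  names(regions) <- vapply(regions, `[[`, character(1L), "region_id")
  counts <- vapply(c(0.3, 0.4, 0.5), function(cut)
    length(cluster_gcfs(regions, cutoff = cut)), integer(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("clustering is invariant to region input order", {
  set.seed(5)
  regions <- lapply(1:8, function(i) {
    doms <- sample(LETTERS[1:5], sample(2:3, 1L))
    mk_region(sprintf("r%02d", i), sprintf("g%d", i),
              lapply(doms, function(d) list("core", d)))
  })
  names(regions) <- vapply(regions, `[[`, character(1L), "region_id")
  g1 <- cluster_gcfs(regions, cutoff = 0.5)
  g2 <- cluster_gcfs(rev(regions), cutoff = 0.5)
  expect_identical(lapply(g1, `[[`, "members"), lapply(g2, `[[`, "members"))
})

test_that("gcf_presence_matrix marks contributing strains once", {
  r1 <- mk_region("r1", "A", list(list("core", "X")))
  r2 <- mk_region("r2", "B", list(list("core", "X")))
  r3 <- mk_region("r3", "A", list(list("core", "X")))
  regions <- list(r1 = r1, r2 = r2, r3 = r3)
  gcfs <- cluster_gcfs(regions, cutoff = 0.4)
  m <- gcf_presence_matrix(gcfs, regions, c("A", "B", "C"))
  expect_equal(unname(unclass(m)[, 1L]), c(1L, 1L, 0L))
  expect_error(gcf_presence_matrix(gcfs, regions, c("A", "Z")),
               "unknown genome")
})

test_that("supercluster with cross-strain evidence splits into its blocks", {
  # genome A fuses blocks X and Y; genome B carries X only, genome C Y only
  fused <- mk_region("scl", "A", list(
    list("core", c("X1", "X2")), list("core", c("X3", "X4")),
    list("other", character(0)),
    list("core", c("Y1", "Y2")), list("core", c("Y3", "Y4"))))
  bx <- mk_region("px", "B", list(list("core", c("X1", "X2")),
                                  list("core", c("X3", "X4"))))
  cy <- mk_region("py", "C", list(list("core", c("Y1", "Y2")),
                                  list("core", c("Y3", "Y4"))))
  regions <- list(scl = fused, px = bx, py = cy)
  gcfs <- list(list(gcf_id = "GCF_px", members = c("scl", "px", "py"),
                    core_domains = character(0)))
  sp <- split_superclusters(gcfs, regions)
  expect_setequal(sp$split_log$parent, "scl")
  expect_setequal(sp$split_log$child, c("scl_s1", "scl_s2"))
  expect_false("scl" %in% names(sp$regions))
  # gene conservation: multiset of gene ids unchanged
  before <- sort(gene_table_from_regions(regions)$gene_id)
  after <- sort(gene_table_from_regions(sp$regions)$gene_id)
  expect_identical(before, after)
  # children carry the right cores
  expect_true(all(grepl("^X", unlist(strsplit(
    sp$regions$scl_s1$genes$domains[sp$regions$scl_s1$genes$category == "core"],
    "|", fixed = TRUE)))))
})

test_that("singleton GCFs and fully aligned members pass through unsplit", {
  fused <- mk_region("solo", "A", list(list("core", "X"), list("core", "Y")))
  sp <- split_superclusters(list(list(gcf_id = "g", members = "solo")),
                            list(solo = fused))
  expect_equal(nrow(sp$split_log), 0L)

  r1 <- mk_region("r1", "A", list(list("core", "X"), list("core", "Y")))
  r2 <- mk_region("r2", "B", list(list("core", "X"), list("core", "Y")))
  sp <- split_superclusters(list(list(gcf_id = "g", members = c("r1", "r2"))),
                            list(r1 = r1, r2 = r2))
  expect_equal(nrow(sp$split_log), 0L)
  expect_setequal(names(sp$regions), c("r1", "r2"))
})

test_that("gene tables round-trip through TSV", {
  fx <- synthesize_curation_fixture(seed = 4, n_planted = 1L,
                                    n_distractors = 2L)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(fx$regions, p)
  back <- read_gene_table(p)
  expect_setequal(names(back), names(fx$regions))
  for (id in names(back)) {
    expect_identical(back[[id]]$genes$gene_id, fx$regions[[id]]$genes$gene_id)
    expect_identical(back[[id]]$genes$domains, fx$regions[[id]]$genes$domains)
    expect_identical(back[[id]]$genome_id, fx$regions[[id]]$genome_id)
  }
})
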