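test_that("RNA count normalization is log2 CPM plus pseudocount", {
  e <- normalize_rna_counts(c(g1 = 500, g2 = 500))
  expect_equal(e["g1", "a"], e["g2", "a"])
  e0 <- normalize_rna_counts(c(g1 = 0, g2 = 100), pseudocount = 1)
  expect_equal(e0["g1", "a"], 0)                     # log2(0 + 1)
  e2 <- normalize_rna_counts(c(g1 = 900000, g2 = 100000), pseudocount = 0)
  expect_equal(e2$a, c(log2(9e5), log2(1e5)))
  expect_error(normalize_rna_counts(numeric(0)), "empty")
  expect_error(normalize_rna_counts(c(g = -1)), "negative")
})

test_that("nCU collapses to genomic CU under equal weights", {
  set.seed(31)
  tx <- simulate_transcriptome(sim_config(seed = 31, n_genes = 40))
  counts <- count_codons(tx$transcripts)
  cu <- genomic_codon_usage(counts)
  expr <- make_expr(setNames(rep(2.5, ncol(counts)), colnames(counts)))
  ncu <- abundance_weighted_usage(counts, expr)
  expect_equal(ncu$cu, cu$cu, tolerance = 1e-12)
  expect_equal(ncu$CU, cu$CU, tolerance = 1e-12)
  expect_equal(sum(ncu$cu), 1, tolerance = 1e-12)
  expect_identical(attr(ncu, "flavor"), "abundance-weighted")
})

test_that("nCU weights codon counts by mRNA abundance", {
  ts <- transcript_set(c(g1 = poly_cds("GCG", 10),
                         g2 = poly_cds("GAC", 10)))
  counts <- count_codons(ts, space = c("GAC", "GCG"))
  ncu <- abundance_weighted_usage(counts, make_expr(c(g1 = 2, g2 = 1)))
  expect_equal(ncu["GCG", "cu"], 2 / 3)
  expect_equal(ncu["GAC", "cu"], 1 / 3)
})

test_that("gene sets are joined on overlap with a message", {
  ts <- transcript_set(c(g1 = poly_cds("GCG", 5),
                         g2 = poly_cds("GAC", 5)))
  counts <- count_codons(ts, space = c("GAC", "GCG"))
  expect_message(
    ncu <- abundance_weighted_usage(counts,
                                    make_expr(c(g1 = 1, g3 = 4))),
    "dropped")
  expect_equal(ncu["GCG", "cu"], 1)
  expect_error(abundance_weighted_usage(counts,
                                        make_expr(c(x = 1))), "shared")
})

test_that("abundance binning partitions genes into near-equal bins", {
  e100 <- normalize_rna_counts(setNames(stats::rpois(100, 50) + 1,
                                        sprintf("g%03d", 1:100)))
  b <- bin_by_abundance(e100, 10)
  expect_true(all(lengths(b) == 10L))

  e4035 <- make_expr(setNames(stats::rnorm(4035), sprintf("g%04d", 1:4035)))
  b2 <- bin_by_abundance(e4035, 10)
  expect_setequal(lengths(b2), c(403L, 404L))
  expect_setequal(unlist(b2), e4035$gene_id)          # partition
  expect_equal(sum(lengths(b2)), 4035L)
  # sorted: every gene in a later bin has abundance >= earlier bin max
  a <- setNames(e4035$a, e4035$gene_id)
  expect_true(max(a[b2[[1]]]) <= min(a[b2[[10]]]))

  expect_error(bin_by_abundance(e100, 1), "at least 2")
  expect_error(bin_by_abundance(make_expr(c(g = 1, h = 2)), 3), "more bins")
})

test_that("bin membership round-trips through the TSV/JSON writers", {
  e <- make_expr(setNames(c(1, 3, 2, 4), sprintf("g%d", 1:4)))
  b <- bin_by_abundance(e, 2)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_bins_tsv(b, e, tsv, js)
  df <- utils::read.delim(tsv)
  expect_setequal(df$gene_id[df$bin == "bin01"], c("g1", "g3"))
  s <- jsonlite::read_json(js)
  expect_equal(s$bin02$n, 2)
  expect_equal(s$bin02$median_a, 3.5)
})

test_that("ties in abundance are broken deterministically by gene id", {
  e <- make_expr(setNames(rep(1, 10), sprintf("g%02d", 10:1)))
  b <- bin_by_abundance(e, 2)
  expect_equal(b[[1]], sprintf("g%02d", 1:5))
  expect_equal(b[[2]], sprintf("g%02d", 6:10))
})

test_that("bin usage comparison is null for identical composition", {
  ts <- transcript_set(setNames(rep(poly_cds(c("GAC", "GCG"), c(1, 9)), 20),
                                sprintf("g%02d", 1:20)))
  counts <- count_codons(ts)
  bins <- bin_by_abundance(
    make_expr(setNames(seq_len(20), sprintf("g%02d", 1:20))), 4)
  cmp <- bin_usage_comparison(bins, counts, "GAC")
  expect_equal(unname(cmp$medians), rep(0.1, 4))
  expect_equal(cmp$p.value, 1, tolerance = 1e-6)
})

test_that("a constructed 2x enrichment shows up as a halved median", {
  # bottom genes: 1 GAC per 20 codons; top genes: 2 per 20
  lo <- poly_cds(c("GAC", "GCG"), c(1, 19))
  hi <- poly_cds(c("GAC", "GCG"), c(2, 18))
  ids <- sprintf("g%02d", 1:40)
  ts <- transcript_set(setNames(c(rep(lo, 20), rep(hi, 20)), ids))
  counts <- count_codons(ts)
  bins <- bin_by_abundance(make_expr(setNames(seq_len(40), ids)), 2)
  cmp <- bin_usage_comparison(bins, counts, "GAC")
  expect_equal(unname(cmp$medians[1] / cmp$medians[2]), 0.5)
  expect_lt(cmp$p.value, 1e-6)
  expect_error(bin_usage_comparison(bins, counts, "AAA"),
               NA)   # codon present in space even if unused
  expect_error(bin_usage_comparison(bins, counts, "TAA"), "not in")
})
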