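uniform_profile <- function(L_codons, d = 1, id = "g1") {
  ribo_profile(setNames(list(rep(d, 3 * L_codons)), id))
}

test_that("coverage filter applies length, skip and mean-coverage rules", {
  short <- ribo_profile(list(g = rep(1000, 90)))
  expect_warning(f1 <- filter_genes(short), "no genes")
  expect_length(f1$density, 0)

  boundary <- uniform_profile(100, d = 40)             # 300 nt, 40 reads/nt
  expect_length(filter_genes(boundary)$density, 1)

  headonly <- ribo_profile(list(g = c(rep(1000, 21), rep(0, 279))))
  expect_warning(f2 <- filter_genes(headonly), "no genes")
  expect_length(f2$density, 0)

  # reads on the skipped 5' region do not rescue a sparse gene,
  # but count fully when after the skip
  tail_cov <- ribo_profile(list(g = c(rep(0, 21), rep(40, 279))))
  expect_length(filter_genes(tail_cov)$density, 1)
})

test_that("metagene recovers a single programmed 5' peak", {
  reads <- ribo_read_table(data.frame(
    gene_id = rep(sprintf("g%d", 1:5), each = 1),
    read_length = 30L, pos5p = -14L, count = 20L))
  off <- metagene_psite_offsets(reads, read_lengths = 30L)
  expect_equal(unname(off$offsets["30"]), 14L)
  expect_equal(sum(off$metagene["30", ]), 5)   # one unit per gene
})

test_that("per-length offsets are recovered from simulated footprints", {
  cfg <- sim_config(seed = 8, n_genes = 120, reads_per_gene_mean = 120)
  tx <- simulate_transcriptome(cfg)
  rib <- simulate_ribo_profile(tx$transcripts, cfg)
  off <- metagene_psite_offsets(rib$reads)
  expect_equal(off$offsets, cfg$psite_offsets_truth,
               ignore_attr = TRUE)
  expect_equal(unname(off$offsets[c("28", "29")]), c(12L, 13L))
})

test_that("per-gene normalization makes the metagene depth-invariant", {
  base <- data.frame(
    gene_id = rep(c("g1", "g2"), each = 3),
    read_length = 30L,
    pos5p = rep(c(-12L, 0L, 30L), 2),
    count = c(5L, 3L, 2L, 5L, 3L, 2L))
  scaled <- base
  scaled$count[scaled$gene_id == "g1"] <-
    scaled$count[scaled$gene_id == "g1"] * 10L
  m1 <- metagene_psite_offsets(ribo_read_table(base), read_lengths = 30L)
  m2 <- metagene_psite_offsets(ribo_read_table(scaled), read_lengths = 30L)
  expect_equal(m1$metagene, m2$metagene)
  expect_equal(sum(m1$metagene["30", ]), 2)
})

test_that("A-site assignment shifts 5' ends by offset + 3", {
  reads <- ribo_read_table(data.frame(gene_id = "g", read_length = 30L,
                                      pos5p = c(-14L, 16L), count = c(4L, 6L)))
  prof <- build_ribo_profile(reads, c("30" = 14L), c(g = 60L))
  expect_equal(prof$density$g[3 + 1], 4)     # -14 + 14 + 3 = nt 3
  expect_equal(prof$density$g[33 + 1], 6)
  expect_equal(sum(prof$density$g), 10)
  # out-of-body reads and unknown lengths are dropped with messages
  reads2 <- ribo_read_table(data.frame(gene_id = "g",
                                       read_length = c(30L, 28L),
                                       pos5p = c(58L, 0L), count = c(1L, 2L)))
  expect_message(expect_message(
    prof2 <- build_ribo_profile(reads2, c("30" = 14L), c(g = 60L)),
    "without an offset"), "outside")
  expect_equal(sum(prof2$density$g), 0)
})

test_that("uniform coverage scores (L-2)/L everywhere, 1 in the interior-only variant", {
  L <- 100
  ts <- transcript_set(c(g1 = paste(rep("GCA", L), collapse = "")))
  prof <- uniform_profile(L, d = 2)
  ps <- pause_scores(prof, ts)
  expect_equal(unname(ps$positional$P), rep((L - 2) / L, L - 2))
  ps_int <- pause_scores(prof, ts, interior_only_F = TRUE)
  expect_equal(unname(ps_int$positional$P), rep(1, L - 2))
})

test_that("a single loaded codon takes the whole normalization budget", {
  L <- 50
  d <- rep(0, 3 * L)
  d[(3 * 9 + 1):(3 * 10)] <- c(2, 3, 5)     # codon index 10
  ts <- transcript_set(c(g1 = paste(rep("GCA", L), collapse = "")))
  ps <- pause_scores(ribo_profile(list(g1 = d)), ts)
  p <- setNames(ps$positional$P, ps$positional$codon_index)
  expect_equal(unname(p["10"]), L - 2)
  expect_equal(unname(p[names(p) != "10"]), rep(0, L - 3))
})

test_that("vectorized pause scores equal the naive per-codon oracle", {
  set.seed(13)
  for (i in 1:20) {
    L <- sample(100:300, 1)
    d <- stats::rpois(3 * L, lambda = stats::runif(1, 0.5, 4))
    ts <- transcript_set(setNames(
      paste(sample(codon_space(), L, replace = TRUE), collapse = ""), "g"))
    ps <- pause_scores(ribo_profile(list(g = d)), ts)
    expect_identical(ps$positional$P, naive_pause(d, L))
  }
})

test_that("pause scores are invariant to scaling a gene's density", {
  set.seed(14)
  L <- 120
  d <- stats::rpois(3 * L, 2)
  ts <- transcript_set(setNames(
    paste(sample(codon_space(), L, replace = TRUE), collapse = ""), "g"))
  p1 <- pause_scores(ribo_profile(list(g = d)), ts)
  p2 <- pause_scores(ribo_profile(list(g = d * 7)), ts)
  expect_equal(p1$positional$P, p2$positional$P)
  expect_equal(p1$genomic, p2$genomic)
})

test_that("genomic pause pooling conventions agree on balanced designs", {
  ts <- transcript_set(c(g1 = paste(rep("GCA", 60), collapse = ""),
                         g2 = paste(rep("GCA", 60), collapse = "")))
  prof <- ribo_profile(list(g1 = rep(1, 180), g2 = rep(2, 180)))
  pooled <- pause_scores(prof, ts, genomic_mean = "pooled")
  per_gene <- pause_scores(prof, ts, genomic_mean = "per_gene")
  expect_equal(pooled$genomic, per_gene$genomic)
})

test_that("amino-acid pauses average synonymous codons", {
  ps <- structure(list(genomic = c(TGG = 1.4, GCA = 1, GCC = 3),
                       positional = NULL, F = c(g = 1),
                       genomic_mean = "pooled"),
                  class = "pause_table")
  aa <- amino_acid_pause(ps)
  expect_equal(aa$pause[aa$amino_acid == "W"], 1.4)  # singleton family
  expect_equal(aa$pause[aa$amino_acid == "A"], 2)
  expect_false(aa$complete_family[aa$amino_acid == "A"])  # 2 of 4 seen
  expect_true(aa$complete_family[aa$amino_acid == "W"])
})

test_that("naive TE is a CPM log-ratio with the expected invariances", {
  ribo <- c(g1 = 100, g2 = 200, g3 = 300)
  expect_equal(unname(translation_efficiency(ribo, ribo, 0)),
               rep(0, 3))
  # scale invariance
  expect_equal(translation_efficiency(ribo, c(g1 = 50, g2 = 100, g3 = 150),
                                      0),
               translation_efficiency(ribo * 13,
                                      c(g1 = 50, g2 = 100, g3 = 150) * 5,
                                      0))
  # doubling one gene's footprints raises its TE by 1 against an oracle
  # recomputation that carries the depth renormalization through
  ribo2 <- ribo
  ribo2["g1"] <- 200
  te <- translation_efficiency(ribo2, ribo, 0)
  oracle <- log2((ribo2 / sum(ribo2) * 1e6) / (ribo / sum(ribo) * 1e6))
  expect_equal(te, oracle)
  expect_error(translation_efficiency(c(a = 1), c(b = 1)), "shared")
})
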