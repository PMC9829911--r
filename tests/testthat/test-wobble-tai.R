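pen <- wobble_penalties()

test_that("decoding map applies Watson-Crick and wobble rules", {
  m <- build_decoding_map(c("GTC"), pen, isotypes = "D")
  expect_equal(m[["GAC"]]$anticodon, "GTC")
  expect_equal(m[["GAC"]]$s, 0)
  expect_equal(m[["GAT"]]$anticodon, "GTC")   # G34:U wobble
  expect_equal(m[["GAT"]]$s, 0.41)
  expect_equal(nrow(m[["GAA"]]), 0L)

  # inosine at A34: ACG (Arg) is the sole decoder of CGA, with the heavy
  # I:A penalty
  set <- mtb_anticodons()
  full <- build_decoding_map(set$anticodon, pen, isotypes = set$amino_acid)
  expect_equal(full[["CGA"]]$anticodon, "ACG")
  expect_equal(full[["CGA"]]$s, 0.9999)
  # lysidine rule routes the Ile CAT decoder to ATA
  expect_true("CAT" %in% full[["ATA"]]$anticodon)
  expect_equal(full[["ATA"]]$s[full[["ATA"]]$anticodon == "CAT"], 0.89)
  # every codon of the 60-space has a decoder in the bundled set
  expect_true(all(vapply(full, nrow, integer(1)) > 0))

  empty <- build_decoding_map(character(0), pen)
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))
  expect_error(build_decoding_map("GXC", pen), "invalid")
})

test_that("absolute adaptiveness is the penalty-weighted abundance sum", {
  map <- make_map(list(
    AAA = data.frame(anticodon = "TTT", s = 0),
    AAG = data.frame(anticodon = c("CTT", "TTT"), s = c(0, 0.5)),
    AAC = data.frame(anticodon = character(0), s = numeric(0))))
  W <- absolute_adaptiveness(map, c(TTT = 4, CTT = 8))
  expect_equal(unname(W["AAA"]), 4)
  expect_equal(unname(W["AAG"]), 8 + 0.5 * 4)   # = 10
  expect_equal(unname(W["AAC"]), 0)
  expect_error(absolute_adaptiveness(map, c(TTT = 4)), "CTT")
})

test_that("TAc normalization and geometric-mean fallback", {
  t1 <- normalize_tac(c(c1 = 10, c2 = 5))
  expect_equal(t1$TAc, c(1, 0.5))
  t2 <- normalize_tac(c(c1 = 4, c2 = 1, c3 = 0))
  expect_equal(t2["c3", "TAc"], sqrt(1 * 0.25))   # geometric mean = 0.5
  expect_error(normalize_tac(c(a = 0, b = 0)), "zero")
  expect_error(normalize_tac(c(a = -1, b = 2)), "negative")
})

test_that("TAc lies in (0, 1] with max exactly 1, over random pools", {
  set.seed(7)
  set <- mtb_anticodons()
  for (i in 1:5) {
    ab <- setNames(stats::runif(nrow(set), 0.5, 16), set$anticodon)
    tac <- compute_tac(
      structure(data.frame(anticodon = set$anticodon,
                           amino_acid = set$amino_acid,
                           abundance = unname(ab)),
                class = c("trna_abundance", "data.frame")))
    expect_equal(max(tac$TAc), 1)
    expect_true(all(tac$TAc > 0 & tac$TAc <= 1))
    expect_equal(nrow(tac), 60L)
  }
})

test_that("equal abundances reproduce the classical copy-number weights", {
  set <- mtb_anticodons()
  ones <- rep(1, nrow(set))
  map <- build_decoding_map(set$anticodon, pen, isotypes = set$amino_acid)
  W <- absolute_adaptiveness(map, setNames(ones, set$anticodon))
  expect_equal(unname(W), unname(oracle_W(set, ones)), tolerance = 1e-12)
})

test_that("W matches the codon-centric oracle on measured abundances too", {
  pool <- simulate_trna_pool(sim_config(seed = 12), profile = "mtb")
  ab <- normalize_trna_counts(pool)
  map <- build_decoding_map(ab$anticodon, pen, isotypes = ab$amino_acid)
  W <- absolute_adaptiveness(map, ab)
  o <- oracle_W(ab, ab$abundance)
  expect_equal(unname(W[names(o)]), unname(o), tolerance = 1e-12)
})

test_that("raising a decoder's abundance never lowers W of its codons", {
  set.seed(11)
  pool_acs <- mtb_anticodons()
  for (i in 1:10) {
    idx <- sample(nrow(pool_acs), 5)
    sub <- pool_acs[idx, ]
    ab <- setNames(stats::runif(5, 1, 10), sub$anticodon)
    map <- build_decoding_map(sub$anticodon, pen,
                              isotypes = sub$amino_acid)
    W0 <- absolute_adaptiveness(map, ab)
    bump <- sample(names(ab), 1)
    ab2 <- ab
    ab2[bump] <- ab2[bump] + 2
    W1 <- absolute_adaptiveness(map, ab2)
    decoded <- names(map)[vapply(map, function(d)
      bump %in% d$anticodon, logical(1))]
    expect_true(all(W1[decoded] >= W0[decoded]))
    expect_equal(W1[setdiff(names(W0), decoded)],
                 W0[setdiff(names(W0), decoded)])
  }
})

test_that("with equal abundances and uniform penalties, W is monotone in decoder count", {
  map <- make_map(list(
    AAA = data.frame(anticodon = "TTT", s = 0.3),
    AAC = data.frame(anticodon = c("TTT", "CTT"), s = c(0.3, 0.3)),
    AAG = data.frame(anticodon = c("TTT", "CTT", "GTT"), s = rep(0.3, 3))))
  W <- absolute_adaptiveness(map, c(TTT = 1, CTT = 1, GTT = 1))
  expect_true(all(diff(W[c("AAA", "AAC", "AAG")]) > 0))
})

test_that("the Mtb-like pool puts CGA last and the Asp/Val/Ala codons high", {
  pool <- simulate_trna_pool(sim_config(seed = 3), profile = "mtb")
  tac <- compute_tac(normalize_trna_counts(pool))
  ranked <- tac$codon[order(-tac$TAc)]
  expect_equal(ranked[length(ranked)], "CGA")
  expect_equal(ranked[1], "GCG")
  # GAC and GTC are the strongest single-decoder codons
  singles <- tac$codon[tac$n_decoders == 1]
  expect_setequal(
    head(singles[order(-tac[singles, "TAc"])], 2), c("GAC", "GTC"))
  expect_true(all(match(c("GAC", "GTC", "GCG"), ranked) <= 15))
})

test_that("penalty files are validated", {
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("pairing:", "  A: {T: 0.2}", "modifications: []"), bad)
  expect_error(wobble_penalties(bad), "Watson-Crick")
})
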