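# Builders for small in-code fixtures and independent oracles.

# expression table with prescribed log2 abundances (bypasses CPM so tests
# can pin a_j exactly)
make_expr <- function(a) {
  structure(data.frame(gene_id = names(a), count = NA_real_,
                       cpm = NA_real_, a = unname(a),
                       row.names = names(a)),
            class = c("expression_table", "data.frame"))
}

# hand-built decoding map: ... = named list codon -> data.frame(anticodon, s)
make_map <- function(decoders) {
  structure(decoders, class = "decoding_map")
}

# independent codon-centric recursion for W, mirroring the classical
# gene-copy-number tAI weight construction: for each codon, look up the
# Watson-Crick and single-wobble anticodon variants and sum (1 - s) times
# the abundance of whichever are present in the pool.
oracle_W <- function(anticodon_df, abundance, space = codon_space()) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ab <- setNames(abundance, anticodon_df$anticodon)
  have <- function(ac) if (ac %in% names(ab)) ab[[ac]] else 0
  vapply(space, function(cod) {
    b <- strsplit(cod, "")[[1]]
    variant <- function(b34) paste0(b34, comp[b[2]], comp[b[1]])
    w <- switch(b[3],
      T = have(variant("A")) + (1 - 0.41) * have(variant("G")),
      C = have(variant("G")) + (1 - 0.28) * have(variant("A")),
      A = have(variant("T")) + (1 - 0.9999) * have(variant("A")),
      G = have(variant("C")) + (1 - 0.68) * have(variant("T")))
    if (cod == "ATA") w <- w + (1 - 0.89) * have("CAT")
    w
  }, numeric(1))
}

# brute-force positional pause scores by explicit per-codon summation
naive_pause <- function(density, L) {
  Fg <- sum(density) / (L - 2)
  vapply(2:(L - 1), function(i) {
    sum(density[(3 * (i - 1) + 1):(3 * i)]) / Fg
  }, numeric(1))
}

# repeat a codon sequence into a CDS body (no start/stop added)
poly_cds <- function(codons, n_each) {
  paste(rep(codons, times = n_each), collapse = "")
}
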