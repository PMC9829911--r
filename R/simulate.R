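#' Simulation configuration
#'
#' Bundles every knob of the seeded generators.  Defaults emulate a
#' desk-scale Mtb-like study: a single-copy tRNA pool whose abundances
#' span an order of magnitude, a few hundred GC-rich-agnostic CDS of
#' 100-300 codons, log-normal mRNA abundance with a 2 log2-unit spread,
#' footprints of 26-35 nt whose P-site offset is read length minus 16,
#' and a strong (25x) initiation dwell that creates the metagene start
#' peak offsets are called from.
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param n_genes Number of CDS (default 400).
#' @param gene_length_range Codon-count interval (default 100-300,
#'   excluding start/stop).
#' @param codon_bias Named probability vector over \code{space} (or a
#'   space x gene matrix for per-gene bias); default uniform.
#' @param trna_abundance_spread Fold-range of tRNA abundances (default
#'   10).
#' @param expression_sd_log2 SD of log2 mRNA abundance (default 2).
#' @param psite_offsets_truth Named integer vector of true offsets per
#'   read length (default \code{read length - 16} for 26-35 nt).
#' @param pause_multipliers Named dwell multipliers per codon (default
#'   all 1).
#' @param reads_per_gene_mean Mean ribo-seq reads per gene (default 100).
#' @param init_pause Dwell multiplier of the initiation position
#'   (default 25).
#' @param rna_depth,trna_depth Library depths (defaults 5e6, 1e6).
#' @param n_replicates tRNA-seq replicates (default 2).
#' @param space Codon space for sequence simulation.
#' @return List of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L, n_genes = 400L,
                       gene_length_range = c(100L, 300L),
                       codon_bias = NULL, trna_abundance_spread = 10,
                       expression_sd_log2 = 2,
                       psite_offsets_truth = stats::setNames(26:35 - 16L,
                                                             26:35),
                       pause_multipliers = NULL,
                       reads_per_gene_mean = 100,
                       init_pause = 25, rna_depth = 5e6,
                       trna_depth = 1e6, n_replicates = 2L,
                       space = codon_space()) {
  if (trna_abundance_spread < 1) stop("spread must be >= 1")
  if (!is.null(pause_multipliers) && any(pause_multipliers <= 0))
    stop("pause multipliers must be positive")
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 gene_length_range = gene_length_range,
                 codon_bias = codon_bias,
                 trna_abundance_spread = trna_abundance_spread,
                 expression_sd_log2 = expression_sd_log2,
                 psite_offsets_truth = psite_offsets_truth,
                 pause_multipliers = pause_multipliers,
                 reads_per_gene_mean = reads_per_gene_mean,
                 init_pause = init_pause, rna_depth = rna_depth,
                 trna_depth = trna_depth, n_replicates = n_replicates,
                 space = space),
            class = "sim_config")
}

#' Bundled single-copy anticodon set
#'
#' A synthetic stand-in for the Mtb single-copy tRNA repertoire: 44
#' unique anticodons with one-letter isotypes and a plausible relative
#' abundance spanning an order of magnitude (Asp-GTC, Val-GAC and
#' Ala-CGC highest; Leu-TAA and Ile-TAT lowest, mirroring the reported
#' rank structure).  The CAT entry is the lysidine-modified Ile decoder;
#' Met tRNAs are omitted because ATG sits outside the 60-codon space.
#'
#' @return Data frame: \code{anticodon}, \code{amino_acid},
#'   \code{relative_abundance}.
#' @export
mtb_anticodons <- function() {
  utils::read.delim(system.file("extdata", "anticodons_mtb_synthetic.tsv",
                                package = "codonopt", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Simulate a tRNA-seq anticodon count table
#'
#' Expected relative abundances are either drawn log-uniformly over the
#' configured fold-spread (\code{profile = "loguniform"}) or taken from
#' the bundled Mtb-like profile (\code{"mtb"}); replicate counts are
#' multinomial draws at the configured depth.
#'
#' @param config A \code{\link{sim_config}}.
#' @param profile Abundance profile, see above.
#' @param anticodons Optional data frame (anticodon, amino_acid[,
#'   relative_abundance]) overriding the bundled set.
#' @return An \code{\link{anticodon_count_table}} with attribute
#'   \code{ground_truth} (anticodon, expected relative abundance).
#' @export
simulate_trna_pool <- function(config,
                               profile = c("loguniform", "mtb"),
                               anticodons = NULL) {
  stopifnot(inherits(config, "sim_config"))
  profile <- match.arg(profile)
  set.seed(config$seed)
  if (is.null(anticodons)) anticodons <- mtb_anticodons()
  n <- nrow(anticodons)
  rel <- switch(profile,
    loguniform = config$trna_abundance_spread ^ stats::runif(n),
    mtb = {
      if (is.null(anticodons$relative_abundance))
        stop("anticodon table lacks a relative_abundance column")
      anticodons$relative_abundance
    })
  prob <- rel / sum(rel)
  rows <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
    cnt <- as.vector(stats::rmultinom(1, size = config$trna_depth,
                                      prob = prob))
    data.frame(anticodon = anticodons$anticodon,
               amino_acid = anticodons$amino_acid,
               replicate = sprintf("rep%d", r), read_count = cnt)
  }))
  out <- anticodon_count_table(rows)
  attr(out, "ground_truth") <- data.frame(
    anticodon = anticodons$anticodon, expected_rel = rel)
  out
}

resolve_bias <- function(config) {
  bias <- config$codon_bias
  if (is.list(bias)) bias <- unlist(bias)
  space <- config$space
  if (is.null(bias))
    bias <- stats::setNames(rep(1 / length(space), length(space)), space)
  if (is.matrix(bias)) {
    if (!setequal(rownames(bias), space))
      stop("codon_bias rows must match the codon space")
    return(bias[space, , drop = FALSE])
  }
  if (!setequal(names(bias), space))
    stop("codon_bias names must match the codon space")
  bias[space]
}

#' Simulate a transcriptome and its RNA-seq counts
#'
#' CDS are built codon by codon from the configured bias (a start codon
#' is prepended and a stop appended so records are well-formed CDS), true
#' mRNA abundances are log-normal with the configured log2 SD, and
#' counts are one multinomial draw at the configured depth.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List: \code{transcripts} (\code{transcript_set}),
#'   \code{rna_counts} (named integer vector), \code{expression}
#'   (\code{expression_table}), \code{truth} (list with
#'   \code{true_abundance}, \code{bias}).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  bias <- resolve_bias(config)
  n <- config$n_genes
  lens <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                 n, replace = TRUE)
  ids <- sprintf("g%04d", seq_len(n))
  seqs <- vapply(seq_len(n), function(j) {
    p <- if (is.matrix(bias)) bias[, j] else bias
    body <- sample(config$space, lens[j], replace = TRUE, prob = p)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }, character(1))
  transcripts <- transcript_set(stats::setNames(seqs, ids),
                                organism = "simulated")
  true_ab <- 2 ^ stats::rnorm(n, mean = 0, sd = config$expression_sd_log2)
  counts <- as.vector(stats::rmultinom(1, size = config$rna_depth,
                                       prob = true_ab / sum(true_ab)))
  names(counts) <- ids
  list(transcripts = transcripts, rna_counts = counts,
       expression = normalize_rna_counts(counts),
       truth = list(true_abundance = stats::setNames(true_ab, ids),
                    bias = bias))
}

triangular_length_weights <- function(lengths, peak = 30L) {
  w <- pmax(1, max(abs(range(lengths) - peak)) + 2 - abs(lengths - peak))
  w / sum(w)
}

#' Simulate ribosome-profiling footprints
#'
#' Ribosomes are placed P-site-wise along each CDS with dwell weight
#' equal to the pause multiplier of the codon in their A site (one codon
#' downstream), times the initiation multiplier at the first codon.
#' Read counts per gene are Poisson around the configured mean; read
#' lengths follow a triangular distribution peaking at 30 nt, and each
#' read's 5' end is the P-site nucleotide minus the true offset of its
#' length.
#'
#' @param transcripts A \code{transcript_set} (e.g. from
#'   \code{\link{simulate_transcriptome}}).
#' @param config A \code{\link{sim_config}}.
#' @return List: \code{reads} (a \code{\link{ribo_read_table}}),
#'   \code{ribo_counts} (named per-gene totals), \code{truth} (list with
#'   \code{offsets}, \code{pause_multipliers}, \code{init_pause}).
#' @export
simulate_ribo_profile <- function(transcripts, config) {
  stopifnot(inherits(transcripts, "transcript_set"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 2000L)
  offsets <- config$psite_offsets_truth
  read_lengths <- as.integer(names(offsets))
  if (anyNA(offsets)) stop("offset truth contains NA")
  lw <- triangular_length_weights(read_lengths)
  mult <- config$pause_multipliers
  rows <- vector("list", length(transcripts))
  ribo_counts <- stats::setNames(integer(length(transcripts)),
                                 names(transcripts))
  for (k in seq_along(transcripts)) {
    g <- names(transcripts)[k]
    s <- transcripts[[k]]
    L <- nchar(s) %/% 3L
    # P-site positions 1..L-1; dwell driven by the A-site codon p+1
    asite_codons <- substring(s, 3L * seq(2L, L) - 2L, 3L * seq(2L, L))
    w <- rep(1, L - 1L)
    if (!is.null(mult)) {
      hit <- asite_codons %in% names(mult)
      w[hit] <- mult[asite_codons[hit]]
    }
    w[1L] <- w[1L] * config$init_pause
    n_reads <- stats::rpois(1, config$reads_per_gene_mean)
    ribo_counts[g] <- n_reads
    if (n_reads == 0L) next
    p <- sample.int(L - 1L, n_reads, replace = TRUE, prob = w)
    l <- sample(read_lengths, n_reads, replace = TRUE, prob = lw)
    pos5p <- 3L * (p - 1L) - offsets[as.character(l)]
    key <- paste(l, pos5p)
    agg <- table(key)
    parts <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
    rows[[k]] <- data.frame(gene_id = g,
                            read_length = as.integer(parts[, 1]),
                            pos5p = as.integer(parts[, 2]),
                            count = as.integer(agg))
  }
  reads <- ribo_read_table(do.call(rbind, rows))
  list(reads = reads, ribo_counts = ribo_counts,
       truth = list(offsets = offsets,
                    pause_multipliers = mult,
                    init_pause = config$init_pause))
}
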