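#' Validate a footprint 5'-end table
#'
#' The reduced representation of a ribo-seq alignment: per gene, per read
#' length, the 5'-end position of each footprint relative to the
#' annotated start codon (0-based; negative = upstream) and how many
#' reads share it.  Minus-strand genes are assumed already flipped to
#' gene-relative coordinates upstream.
#'
#' @param reads Data frame with columns \code{gene_id},
#'   \code{read_length}, \code{pos5p}, \code{count}.
#' @return The validated data frame, class \code{"ribo_reads"}.
#' @export
ribo_read_table <- function(reads) {
  need <- c("gene_id", "read_length", "pos5p", "count")
  if (!all(need %in% names(reads)))
    stop("missing column(s): ", paste(setdiff(need, names(reads)),
                                      collapse = ", "))
  if (any(reads$count < 0)) stop("negative read count")
  structure(as.data.frame(reads), class = c("ribo_reads", "data.frame"))
}

#' Read a footprint 5'-end TSV
#'
#' @param path Tab-separated file with header columns gene_id,
#'   read_length, pos5p, count.
#' @return A \code{\link{ribo_read_table}}.
#' @export
read_ribo_reads <- function(path) {
  ribo_read_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Metagene P-site offsets per read length
#'
#' For each read length, 5'-end counts of reads landing in a window
#' around annotated start codons (default the half-open window
#' [-50, +200), 250 positions) are collected per gene, each gene's
#' vector is normalized to sum 1 so deeply covered genes do not dominate,
#' and the metagene is the column-wise sum across genes.  The P-site
#' offset is the distance from the initiation peak (the metagene maximum)
#' upstream to the annotated start.
#'
#' @param reads A \code{\link{ribo_read_table}}.
#' @param window Integer pair, half-open gene-relative window
#'   (default \code{c(-50, 200)}).
#' @param read_lengths Lengths to estimate (default \code{26:35}).
#' @return List of class \code{"psite_offsets"}: \code{offsets} (named
#'   integer vector, \code{NA} where a length had no reads or an
#'   implausible downstream peak) and \code{metagene} (matrix, one row
#'   per read length, columns named by window position).
#' @export
metagene_psite_offsets <- function(reads, window = c(-50, 200),
                                   read_lengths = 26:35) {
  stopifnot(inherits(reads, "ribo_reads"), length(window) == 2,
            window[1] < window[2])
  positions <- seq(window[1], window[2] - 1L)
  mg <- matrix(0, nrow = length(read_lengths), ncol = length(positions),
               dimnames = list(as.character(read_lengths),
                               as.character(positions)))
  offsets <- stats::setNames(rep(NA_integer_, length(read_lengths)),
                             as.character(read_lengths))
  for (li in seq_along(read_lengths)) {
    l <- read_lengths[li]
    sub <- reads[reads$read_length == l & reads$pos5p >= window[1] &
                   reads$pos5p < window[2] & reads$count > 0, ]
    if (nrow(sub) == 0L) {
      message("no reads of length ", l, " in the start window")
      next
    }
    gene_tot <- tapply(sub$count, sub$gene_id, sum)
    w <- sub$count / gene_tot[as.character(sub$gene_id)]
    col <- sub$pos5p - window[1] + 1L
    acc <- tapply(w, col, sum)
    mg[li, as.integer(names(acc))] <- acc
    peak <- positions[which.max(mg[li, ])]
    if (peak > 0) {
      warning("length ", l, ": initiation peak downstream of the start (",
              peak, "); offset set NA")
    } else offsets[li] <- -peak
  }
  structure(list(offsets = offsets, metagene = mg),
            class = "psite_offsets")
}

#' @export
print.psite_offsets <- function(x, ...) {
  cat("psite_offsets:\n")
  print(x$offsets)
  invisible(x)
}

#' Build per-gene A-site density vectors from 5'-end reads
#'
#' Each read is assigned to a single nucleotide:
#' \code{pos5p + offset[read_length] + asite_shift}.  Offsets place the
#' P-site; the default \code{asite_shift = 3} moves one codon downstream
#' to the A site, where decoding (and hence codon-specific dwell)
#' happens.  Reads of a length without an offset, or landing outside the
#' gene body, are dropped with a message.
#'
#' @param reads A \code{\link{ribo_read_table}}.
#' @param offsets A \code{\link{metagene_psite_offsets}} result or named
#'   integer vector (names = read lengths).
#' @param gene_lengths_nt Named integer vector of CDS lengths in
#'   nucleotides (multiples of 3).
#' @param asite_shift Nucleotides added past the P-site offset
#'   (default 3; use 0 for P-site-resolved density).
#' @return Object of class \code{"ribo_profile"}: list with
#'   \code{density} (named list of per-nucleotide numeric vectors) and
#'   \code{gene_lengths_codons}.
#' @export
build_ribo_profile <- function(reads, offsets, gene_lengths_nt,
                               asite_shift = 3L) {
  stopifnot(inherits(reads, "ribo_reads"))
  if (inherits(offsets, "psite_offsets")) offsets <- offsets$offsets
  if (any(gene_lengths_nt %% 3L != 0L))
    stop("gene lengths must be multiples of 3")
  off <- offsets[as.character(reads$read_length)]
  drop_len <- is.na(off)
  if (any(drop_len))
    message(sum(reads$count[drop_len]),
            " read(s) of length(s) without an offset dropped")
  reads <- reads[!drop_len, ]
  off <- off[!drop_len]
  nt <- reads$pos5p + off + asite_shift
  len <- gene_lengths_nt[as.character(reads$gene_id)]
  inside <- !is.na(len) & nt >= 0L & nt < len
  if (any(!inside))
    message(sum(reads$count[!inside]),
            " read(s) mapping outside the gene body dropped")
  reads <- reads[inside, ]
  nt <- nt[inside]
  density <- lapply(stats::setNames(names(gene_lengths_nt),
                                    names(gene_lengths_nt)),
                    function(g) numeric(gene_lengths_nt[[g]]))
  if (nrow(reads)) {
    agg <- tapply(reads$count, list(reads$gene_id, nt), sum)
    for (g in rownames(agg)) {
      cols <- !is.na(agg[g, ])
      density[[g]][as.integer(colnames(agg)[cols]) + 1L] <- agg[g, cols]
    }
  }
  structure(list(density = density,
                 gene_lengths_codons = gene_lengths_nt %/% 3L),
            class = "ribo_profile")
}

#' Construct a ribo profile directly from density vectors
#'
#' @param density Named list of per-nucleotide non-negative vectors whose
#'   lengths are multiples of 3.
#' @return A \code{"ribo_profile"}.
#' @export
ribo_profile <- function(density) {
  lens <- lengths(density)
  if (any(lens %% 3L != 0L)) stop("density lengths must be multiples of 3")
  if (any(vapply(density, function(d) any(d < 0), logical(1))))
    stop("negative density")
  structure(list(density = density,
                 gene_lengths_codons = lens %/% 3L),
            class = "ribo_profile")
}

#' @export
print.ribo_profile <- function(x, ...) {
  cat("ribo_profile:", length(x$density), "genes;",
      format(sum(unlist(lapply(x$density, sum)))), "reads assigned\n")
  invisible(x)
}

#' Coverage-filter a ribo profile
#'
#' Keeps genes at least \code{min_len_nt} long whose mean per-nucleotide
#' read count, computed over the positions after the first
#' \code{skip_5p_nt} nucleotides (where initiation artefacts concentrate),
#' is at least \code{min_mean_cov}.  Both thresholds are inclusive.
#'
#' @param profile A \code{ribo_profile}.
#' @param min_len_nt Minimum CDS length in nt (default 100).
#' @param skip_5p_nt Leading nucleotides excluded from the coverage mean
#'   (default 21).
#' @param min_mean_cov Minimum mean reads per nucleotide (default 40).
#' @return The filtered \code{ribo_profile} (possibly empty, with a
#'   warning).
#' @export
filter_genes <- function(profile, min_len_nt = 100, skip_5p_nt = 21,
                         min_mean_cov = 40) {
  stopifnot(inherits(profile, "ribo_profile"))
  keep <- vapply(profile$density, function(d) {
    if (length(d) < min_len_nt) return(FALSE)
    tail_d <- d[(skip_5p_nt + 1L):length(d)]
    mean(tail_d) >= min_mean_cov
  }, logical(1))
  if (!any(keep)) warning("no genes pass the coverage filter")
  ribo_profile(profile$density[keep])
}

#' Codon-resolved pause scores
#'
#' Per gene g, the density vector is split into codon chunks; the
#' normalization factor is \code{F_g = sum(R_g) / (L_g - 2)} (total reads
#' over interior length, the two terminal codons being excluded from
#' scoring), and the positional pause score of interior codon i is
#' \code{P_gi = sum(C_gi) / F_g}.  A codon's genomic pause score pools
#' the positional scores of every interior occurrence across genes
#' (\code{genomic_mean = "pooled"}, default) or averages per-gene means
#' (\code{"per_gene"}).
#'
#' @param profile A (typically filtered) \code{ribo_profile} holding
#'   A-site-assigned density.
#' @param transcripts A \code{transcript_set} giving codon identities;
#'   must cover the profiled genes.
#' @param genomic_mean Pooling convention, see above.
#' @param skip_5p_codons Leading codons excluded from positional scoring
#'   (default 1: only the start codon, the literal convention).  The
#'   A-site density one codon into the CDS carries the initiation dwell
#'   rather than codon-specific elongation dwell, so codon-level
#'   comparisons are cleaner with a wider exclusion, e.g. 7 codons
#'   (21 nt, matching the coverage-filter skip).
#' @param interior_only_F Use only scored positions in the numerator of
#'   \code{F_g} (variant; default \code{FALSE} computes the literal
#'   full-vector sum, under which uniform coverage scores
#'   \code{(L-2)/L}, not 1).
#' @return List of class \code{"pause_table"}: \code{positional} (data
#'   frame gene_id, codon_index (1-based), codon, P), \code{genomic}
#'   (named vector), \code{F} (named per-gene vector).
#' @export
pause_scores <- function(profile, transcripts,
                         genomic_mean = c("pooled", "per_gene"),
                         skip_5p_codons = 1L, interior_only_F = FALSE) {
  stopifnot(inherits(profile, "ribo_profile"),
            inherits(transcripts, "transcript_set"))
  genomic_mean <- match.arg(genomic_mean)
  genes <- names(profile$density)
  missing <- setdiff(genes, names(transcripts))
  if (length(missing))
    stop("profiled gene(s) absent from the CDS set: ",
         paste(utils::head(missing, 5), collapse = ", "))
  pos_list <- vector("list", length(genes))
  Fg <- stats::setNames(rep(NA_real_, length(genes)), genes)
  for (k in seq_along(genes)) {
    g <- genes[k]
    d <- profile$density[[g]]
    L <- length(d) %/% 3L
    if (L < skip_5p_codons + 2L) next
    chunk <- colSums(matrix(d, nrow = 3L))
    interior <- (skip_5p_codons + 1L):(L - 1L)
    f <- (if (interior_only_F) sum(chunk[interior]) else sum(d)) / (L - 2L)
    if (f == 0) {
      warning("gene ", g, " has zero coverage; skipped")
      next
    }
    Fg[g] <- f
    codons <- substring(transcripts[[g]], 3L * (interior - 1L) + 1L,
                        3L * interior)
    pos_list[[k]] <- data.frame(gene_id = g, codon_index = interior,
                                codon = codons, P = chunk[interior] / f)
  }
  positional <- do.call(rbind, pos_list)
  if (is.null(positional) || nrow(positional) == 0L)
    stop("no scorable genes")
  genomic <- switch(genomic_mean,
    pooled = tapply(positional$P, positional$codon, mean),
    per_gene = {
      per <- tapply(positional$P,
                    list(positional$codon, positional$gene_id),
                    mean)
      apply(per, 1L, mean, na.rm = TRUE)
    })
  structure(list(positional = positional,
                 genomic = c(genomic), F = Fg[!is.na(Fg)],
                 genomic_mean = genomic_mean),
            class = "pause_table")
}

#' @export
print.pause_table <- function(x, ...) {
  top <- utils::head(sort(x$genomic, decreasing = TRUE), 5)
  cat("pause_table:", length(x$F), "genes,", length(x$genomic),
      "codons (", x$genomic_mean, "mean )\n highest:",
      paste(sprintf("%s=%.2f", names(top), top), collapse = " "), "\n")
  invisible(x)
}

#' Average pause score per amino acid
#'
#' Unweighted mean of the genomic pause scores of the synonymous codons
#' of each amino acid; families with unobserved codons are averaged over
#' the observed ones and flagged.
#'
#' @param table A \code{\link{pause_scores}} result.
#' @return Data frame with columns \code{amino_acid}, \code{pause},
#'   \code{n_codons_observed}, \code{n_codons_family},
#'   \code{complete_family}.
#' @export
amino_acid_pause <- function(table) {
  stopifnot(inherits(table, "pause_table"))
  observed <- names(table$genomic)
  aa_obs <- codon_to_aa(observed)
  fam <- table(codon_to_aa(setdiff(ALL_CODONS, STOP_CODONS)))
  pause <- tapply(table$genomic, aa_obs, mean)
  n_obs <- tapply(table$genomic, aa_obs, length)
  df <- data.frame(amino_acid = names(pause), pause = unname(c(pause)),
                   n_codons_observed = unname(c(n_obs)),
                   n_codons_family = unname(c(fam[names(pause)])))
  df$complete_family <- df$n_codons_observed == df$n_codons_family
  df[order(df$amino_acid), ]
}

#' Naive translation efficiency
#'
#' \code{TE_j = log2((ribo CPM_j + pc) / (RNA CPM_j + pc))} over genes
#' present in both tables.  This is a plain footprint-to-mRNA density
#' ratio; it carries no dispersion model or significance assessment, only
#' a per-gene effect size.
#'
#' @param ribo_counts,rna_counts Named numeric vectors of per-gene read
#'   counts.
#' @param pseudocount CPM offset (default 1).
#' @return Named numeric vector of per-gene log2 TE.
#' @export
translation_efficiency <- function(ribo_counts, rna_counts,
                                   pseudocount = 1) {
  shared <- intersect(names(ribo_counts), names(rna_counts))
  if (length(shared) == 0L) stop("no genes shared between the two tables")
  rc <- ribo_counts[shared] / sum(ribo_counts) * 1e6
  mc <- rna_counts[shared] / sum(rna_counts) * 1e6
  stats::setNames(log2((rc + pseudocount) / (mc + pseudocount)), shared)
}

#' Write pause tables to TSV / offsets to JSON
#'
#' @param pause A \code{pause_table}.
#' @param codon_path,aa_path TSV output paths (NULL to skip).
#' @param offsets Optional \code{psite_offsets} written to
#'   \code{offsets_json}.
#' @param offsets_json JSON output path (NULL to skip).
#' @export
write_pause_tsv <- function(pause, codon_path = NULL, aa_path = NULL,
                            offsets = NULL, offsets_json = NULL) {
  if (!is.null(codon_path)) {
    df <- data.frame(codon = names(pause$genomic),
                     amino_acid = codon_to_aa(names(pause$genomic)),
                     pause = unname(pause$genomic))
    utils::write.table(df[order(df$codon), ], codon_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(aa_path))
    utils::write.table(amino_acid_pause(pause), aa_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(offsets) && !is.null(offsets_json))
    jsonlite::write_json(as.list(offsets$offsets), offsets_json,
                         auto_unbox = TRUE, digits = NA)
  invisible(pause)
}
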