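#' Normalize RNA-seq counts to log2 CPM
#'
#' Per-gene abundance \code{a_j = log2(CPM_j + pseudocount)}.  Because
#' abundance enters the demand-weighted usage only through relative
#' weights, any monotone library-size normalization gives rank-identical
#' bins; CPM is the default for its simplicity.
#'
#' @param counts Named numeric vector (or single-column data frame with
#'   gene ids as row names / a \code{gene_id}+\code{count} data frame) of
#'   raw read counts.
#' @param pseudocount CPM offset before the log (default 1).
#' @return Data frame of class \code{"expression_table"} with columns
#'   \code{gene_id}, \code{count}, \code{cpm}, \code{a}.
#' @examples
#' normalize_rna_counts(c(g1 = 900000, g2 = 100000))
#' @export
normalize_rna_counts <- function(counts, pseudocount = 1) {
  if (is.data.frame(counts)) {
    if (all(c("gene_id", "count") %in% names(counts)))
      counts <- stats::setNames(counts$count, counts$gene_id)
    else
      counts <- stats::setNames(counts[[1]], rownames(counts))
  }
  if (length(counts) == 0L) stop("empty count table")
  if (any(counts < 0)) stop("negative counts")
  cpm <- counts / sum(counts) * 1e6
  a <- log2(cpm + pseudocount)
  structure(data.frame(gene_id = names(counts), count = unname(counts),
                       cpm = unname(cpm), a = unname(a),
                       row.names = names(counts)),
            class = c("expression_table", "data.frame"),
            pseudocount = pseudocount)
}

#' Read a gene count TSV (gene_id, count)
#'
#' @param path Path to a tab-separated file with header.
#' @param pseudocount Passed to \code{\link{normalize_rna_counts}}.
#' @return An \code{expression_table}.
#' @export
read_rna_counts <- function(path, pseudocount = 1) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  normalize_rna_counts(stats::setNames(df$count, df$gene_id), pseudocount)
}

#' Abundance-weighted (demand) codon usage
#'
#' Each gene's codon counts are weighted by its log2 abundance
#' \code{a_j}, giving the transcriptome-level demand for each codon:
#' \code{ncu_i = sum_j C_ij a_j / sum_ij C_ij a_j}, rescaled to
#' \code{nCU_i = ncu_i / max(ncu)}.  Genes present in only one of the two
#' inputs are dropped with a message.
#'
#' @param counts A \code{\link{count_codons}} matrix.
#' @param expr An \code{\link{normalize_rna_counts}} table.
#' @return A \code{codon_usage} with \code{flavor =
#'   "abundance-weighted"} (columns still named \code{cu}/\code{CU}; they
#'   hold \code{ncu}/\code{nCU}).
#' @export
abundance_weighted_usage <- function(counts, expr) {
  stopifnot(inherits(counts, "codon_counts"),
            inherits(expr, "expression_table"))
  shared <- intersect(colnames(counts), expr$gene_id)
  if (length(shared) == 0L) stop("no genes shared between counts and expression")
  dropped <- (ncol(counts) - length(shared)) +
    (nrow(expr) - length(shared))
  if (dropped > 0)
    message(dropped, " gene(s) present in only one input dropped")
  a <- stats::setNames(expr$a, expr$gene_id)[shared]
  weighted <- as.vector(counts[, shared, drop = FALSE] %*% a)
  names(weighted) <- rownames(counts)
  denom <- sum(weighted)
  if (denom == 0) stop("zero total weighted codon count")
  new_codon_usage(names(weighted), weighted / denom,
                  flavor = "abundance-weighted")
}

#' Partition genes into abundance bins
#'
#' Genes are sorted by abundance \code{a} (ties broken by gene id for
#' determinism) and split lowest-to-highest into \code{n_bins} groups
#' whose sizes differ by at most one.
#'
#' @param expr An \code{expression_table}.
#' @param n_bins Number of bins (default 10).
#' @return List of class \code{"abundance_bins"}: character vectors of
#'   gene ids, element 1 the least abundant bin.
#' @export
bin_by_abundance <- function(expr, n_bins = 10) {
  stopifnot(inherits(expr, "expression_table"))
  if (n_bins < 2) stop("n_bins must be at least 2")
  n <- nrow(expr)
  if (n_bins > n) stop("more bins than genes")
  ord <- order(expr$a, expr$gene_id)
  ids <- expr$gene_id[ord]
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins <- split(ids, rep(seq_len(n_bins), sizes))
  names(bins) <- sprintf("bin%02d", seq_len(n_bins))
  structure(bins, class = "abundance_bins")
}

#' @export
print.abundance_bins <- function(x, ...) {
  cat("abundance_bins:", length(x), "bins, sizes",
      paste(range(lengths(x)), collapse = "-"),
      "(low to high abundance)\n")
  invisible(x)
}

#' Write bin membership (TSV) and bin statistics (JSON)
#'
#' @param bins An \code{abundance_bins} partition.
#' @param expr The \code{expression_table} the bins were formed on.
#' @param path Output TSV path (columns gene_id, bin).
#' @param json_path Optional JSON path for per-bin summary statistics
#'   (size, median and range of log2 abundance).
#' @export
write_bins_tsv <- function(bins, expr, path, json_path = NULL) {
  stopifnot(inherits(bins, "abundance_bins"))
  df <- data.frame(gene_id = unlist(bins, use.names = FALSE),
                   bin = rep(names(bins), lengths(bins)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    a <- stats::setNames(expr$a, expr$gene_id)
    stats_list <- lapply(bins, function(ids) {
      list(n = length(ids), median_a = stats::median(a[ids]),
           min_a = min(a[ids]), max_a = max(a[ids]))
    })
    jsonlite::write_json(stats_list, json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Compare per-mRNA usage of one codon between abundance bins
#'
#' Per-mRNA frequency of the codon is its count divided by the gene's
#' total counted codons.  Reports the per-bin median frequency and a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test of the bottom
#' (least-abundant) against the top (most-abundant) bin.
#'
#' @param bins An \code{\link{bin_by_abundance}} result.
#' @param counts A \code{codon_counts} matrix covering the binned genes.
#' @param codon Codon to compare (must be a row of \code{counts}).
#' @return List of class \code{"bin_usage_comparison"}: \code{codon},
#'   \code{medians} (per bin), \code{p.value} (bottom vs top),
#'   \code{frequencies} (list of per-bin numeric vectors).
#' @export
bin_usage_comparison <- function(bins, counts, codon) {
  stopifnot(inherits(bins, "abundance_bins"),
            inherits(counts, "codon_counts"))
  if (!codon %in% rownames(counts))
    stop("codon ", codon, " not in the counted space")
  if (any(lengths(bins) == 0L)) stop("empty bin")
  totals <- colSums(counts)
  freq_all <- counts[codon, ] / totals
  freqs <- lapply(bins, function(ids) {
    miss <- setdiff(ids, colnames(counts))
    if (length(miss))
      stop("gene(s) missing from count matrix: ",
           paste(utils::head(miss, 5), collapse = ", "))
    unname(freq_all[ids])
  })
  med <- vapply(freqs, stats::median, numeric(1))
  lo <- freqs[[1L]]
  hi <- freqs[[length(freqs)]]
  p <- if (stats::var(c(lo, hi)) == 0) 1   # every value tied: null exactly
       else stats::wilcox.test(lo, hi, alternative = "two.sided",
                               exact = FALSE)$p.value
  structure(list(codon = codon, medians = med, p.value = p,
                 frequencies = freqs),
            class = "bin_usage_comparison")
}

#' @export
print.bin_usage_comparison <- function(x, ...) {
  cat("codon", x$codon, "| median per-mRNA frequency, bottom bin:",
      format(x$medians[1], digits = 3), "top bin:",
      format(x$medians[length(x$medians)], digits = 3),
      "| Mann-Whitney p =", format(x$p.value, digits = 3), "\n")
  invisible(x)
}
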