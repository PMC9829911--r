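#' Count codons across a CDS set
#'
#' Counts in-frame (frame 0) codon occurrences per gene, restricted to a
#' codon space.  Stop codons and any codon outside the space are dropped
#' both from the matrix and from the grand total \code{N}.  The start codon
#' of each CDS is included by default; set \code{include_start = FALSE} to
#' drop the first codon of every record.
#'
#' @param transcripts A \code{\link{transcript_set}}.
#' @param space Character vector of codons to count
#'   (default \code{codon_space("sense60")}).
#' @param include_start Keep the first codon of each CDS?  Default
#'   \code{TRUE}.
#' @return Integer matrix of class \code{"codon_counts"} with one row per
#'   codon in \code{space} (row order = \code{space}) and one column per
#'   gene.
#' @examples
#' ts <- transcript_set(c(g1 = "GCGGCGTAA"))
#' cc <- count_codons(ts)
#' cc["GCG", "g1"]   # 2; the stop codon is excluded
#' @export
count_codons <- function(transcripts, space = codon_space(),
                         include_start = TRUE) {
  stopifnot(inherits(transcripts, "transcript_set"))
  if (length(transcripts) == 0L) {
    m <- matrix(0L, nrow = length(space), ncol = 0L,
                dimnames = list(space, character(0)))
    return(structure(m, class = c("codon_counts", class(m)),
                     codon_space = space))
  }
  seqs <- unclass(transcripts)
  if (!include_start)
    seqs <- substring(seqs, 4L)
  x <- Biostrings::DNAStringSet(seqs)
  freq <- Biostrings::trinucleotideFrequency(x, step = 3)
  m <- t(freq)[space, , drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- names(transcripts)
  structure(m, class = c("codon_counts", class(m)), codon_space = space)
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("codon_counts:", nrow(x), "codons x", ncol(x), "genes; N =",
      sum(x), "\n")
  invisible(x)
}

#' Genomic codon usage
#'
#' For codon i, \code{cu_i} is its share of all counted codons,
#' \code{cu_i = sum_j C_ij / N}, and \code{CU_i = cu_i / max(cu)} rescales
#' so the most used codon is 1.
#'
#' @param counts A \code{\link{count_codons}} matrix.
#' @return A data frame of class \code{"codon_usage"} with columns
#'   \code{codon}, \code{amino_acid}, \code{cu} (raw fraction, sums to 1)
#'   and \code{CU} (fraction of the maximum); attribute
#'   \code{flavor = "genomic"}.
#' @export
genomic_codon_usage <- function(counts) {
  stopifnot(inherits(counts, "codon_counts"))
  tot <- rowSums(counts)
  N <- sum(tot)
  if (N == 0) stop("no codons counted")
  cu <- tot / N
  new_codon_usage(names(tot), cu, flavor = "genomic")
}

new_codon_usage <- function(codons, raw, flavor) {
  df <- data.frame(codon = codons,
                   amino_acid = codon_to_aa(codons),
                   cu = unname(raw),
                   CU = unname(raw / max(raw)),
                   row.names = codons)
  structure(df, class = c("codon_usage", "data.frame"), flavor = flavor)
}

#' @export
print.codon_usage <- function(x, ...) {
  cat("codon_usage (", attr(x, "flavor"), "), ", nrow(x), " codons\n",
      sep = "")
  print.data.frame(utils::head(x[order(-x$cu), ], 5), digits = 4)
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Rank-correlate two codon-usage (or usage-like) vectors
#'
#' Spearman rank correlation over a shared codon space, as used to compare
#' usage between genomes, between abundance bins, or usage against TAc.
#'
#' @param a,b Objects with \code{codon} and a value column: a
#'   \code{codon_usage} (uses \code{cu}), a \code{tac} table (uses
#'   \code{TAc}), or a named numeric vector.
#' @param value_a,value_b Optional column names overriding the default
#'   value column.
#' @return List of class \code{"usage_comparison"}: \code{estimate} (rho),
#'   \code{p.value}, and \code{table} (codon, value_a, value_b).
#' @export
compare_usage <- function(a, b, value_a = NULL, value_b = NULL) {
  va <- usage_values(a, value_a)
  vb <- usage_values(b, value_b)
  if (!setequal(names(va), names(vb))) {
    extra_a <- setdiff(names(va), names(vb))
    extra_b <- setdiff(names(vb), names(va))
    stop("codon spaces differ; only in first: ",
         paste(extra_a, collapse = ","), "; only in second: ",
         paste(extra_b, collapse = ","))
  }
  vb <- vb[names(va)]
  ct <- stats::cor.test(va, vb, method = "spearman", exact = FALSE)
  structure(list(estimate = unname(ct$estimate),
                 p.value = ct$p.value,
                 table = data.frame(codon = names(va),
                                    value_a = unname(va),
                                    value_b = unname(vb))),
            class = "usage_comparison")
}

usage_values <- function(x, column = NULL) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x)) {
    if (is.null(column))
      column <- intersect(c("cu", "TAc"), names(x))[1]
    if (is.na(column) || is.null(x[[column]]))
      stop("cannot find a value column in usage-like object")
    v <- x[[column]]
    names(v) <- x$codon
    return(v)
  }
  stop("unsupported usage-like object of class ", class(x)[1])
}

#' @export
print.usage_comparison <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.3g over %d codons\n",
              x$estimate, x$p.value, nrow(x$table)))
  invisible(x)
}

#' Write a usage vector to TSV
#'
#' Columns: codon, amino_acid, cu, CU (raw column is named \code{ncu}/
#' \code{nCU} for the abundance-weighted flavor).
#'
#' @param usage A \code{codon_usage}.
#' @param path Output path.
#' @export
write_usage_tsv <- function(usage, path) {
  df <- as.data.frame(usage)
  if (identical(attr(usage, "flavor"), "abundance-weighted"))
    names(df)[names(df) %in% c("cu", "CU")] <- c("ncu", "nCU")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
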