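#' Build a per-anticodon tRNA read-count table
#'
#' Holds sequencing read counts per anticodon and replicate, the raw output
#' of a hybridization-based tRNA-seq experiment, plus the isotype (amino
#' acid) each anticodon is charged with.
#'
#' @param counts Data frame with columns \code{anticodon},
#'   \code{amino_acid}, \code{replicate}, \code{read_count}.
#' @return The validated data frame with class
#'   \code{"anticodon_counts"} prepended.
#' @export
anticodon_count_table <- function(counts) {
  need <- c("anticodon", "amino_acid", "replicate", "read_count")
  if (!all(need %in% names(counts)))
    stop("missing column(s): ", paste(setdiff(need, names(counts)),
                                      collapse = ", "))
  counts$anticodon <- toupper(gsub("U", "T", counts$anticodon))
  if (any(!grepl("^[ACGT]{3}$", counts$anticodon)))
    stop("anticodons must be DNA 3-mers")
  if (any(counts$read_count < 0)) stop("negative read count")
  iso <- tapply(counts$amino_acid, counts$anticodon,
                function(a) length(unique(a)))
  if (any(iso > 1))
    stop("anticodon(s) mapped to more than one isotype: ",
         paste(names(iso)[iso > 1], collapse = ", "))
  structure(as.data.frame(counts), class = c("anticodon_counts",
                                             "data.frame"))
}

#' Read an anticodon count TSV
#'
#' Expected columns: anticodon, amino_acid, replicate, read_count.
#'
#' @param path Path to a tab-separated file with header.
#' @return An \code{\link{anticodon_count_table}}.
#' @export
read_anticodon_counts <- function(path) {
  anticodon_count_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' tRNA abundance from anticodon read counts
#'
#' Per replicate, read counts are scaled to counts per million (CPM) so
#' replicates of unequal depth are comparable; replicate CPMs are averaged
#' and abundance is \code{log2(mean CPM + pseudocount)}.  The log2 scale is
#' what enters the adaptiveness sum \code{W_i}.  Anticodons with zero reads
#' are retained (their abundance comes from the pseudocount alone), so the
#' codons they decode fall through to the zero-adaptiveness fallback rather
#' than disappearing.  A negative abundance (possible only when
#' \code{pseudocount < 1} meets a near-zero CPM) is floored at 0 with a
#' warning, keeping \code{W} non-negative.
#'
#' @param table An \code{\link{anticodon_count_table}}.
#' @param pseudocount Non-negative CPM offset before the log (default 1).
#' @return Data frame of class \code{"trna_abundance"} with columns
#'   \code{anticodon}, \code{amino_acid}, \code{mean_cpm},
#'   \code{abundance}, ordered by decreasing abundance.
#' @examples
#' tab <- anticodon_count_table(data.frame(
#'   anticodon = c("GTC", "GAC"), amino_acid = c("D", "V"),
#'   replicate = "r1", read_count = c(900, 100)))
#' normalize_trna_counts(tab)
#' @export
normalize_trna_counts <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "anticodon_counts"), pseudocount >= 0)
  if (all(table$read_count == 0)) stop("all-zero count table")
  depth <- tapply(table$read_count, table$replicate, sum)
  if (any(depth == 0)) {
    warning("replicate(s) with zero total reads dropped: ",
            paste(names(depth)[depth == 0], collapse = ", "))
    table <- table[table$replicate %in% names(depth)[depth > 0], ]
    depth <- depth[depth > 0]
  }
  cpm <- table$read_count / depth[as.character(table$replicate)] * 1e6
  anticodons <- sort(unique(table$anticodon))
  mean_cpm <- vapply(anticodons, function(ac) {
    mean(tapply(cpm[table$anticodon == ac],
                table$replicate[table$anticodon == ac], sum))
  }, numeric(1))
  # anticodon absent from a replicate counts as zero there
  n_rep <- length(depth)
  per_ac_reps <- tapply(table$replicate, table$anticodon,
                        function(r) length(unique(r)))[anticodons]
  mean_cpm <- mean_cpm * per_ac_reps / n_rep
  abundance <- log2(mean_cpm + pseudocount)
  if (any(abundance < 0)) {
    warning(sum(abundance < 0),
            " anticodon(s) with negative log2 abundance floored at 0")
    abundance[abundance < 0] <- 0
  }
  iso <- table$amino_acid[match(anticodons, table$anticodon)]
  out <- data.frame(anticodon = anticodons, amino_acid = iso,
                    mean_cpm = unname(mean_cpm),
                    abundance = unname(abundance),
                    row.names = anticodons)
  out <- out[order(-out$abundance), ]
  structure(out, class = c("trna_abundance", "data.frame"),
            normalization = sprintf("mean CPM over %d replicate(s), log2(+%g)",
                                    n_rep, pseudocount))
}

#' @export
print.trna_abundance <- function(x, ...) {
  cat("trna_abundance:", nrow(x), "anticodons;",
      attr(x, "normalization"), "\n")
  print.data.frame(utils::head(x, 5), digits = 4)
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Write a tRNA abundance table to TSV
#'
#' @param abundance A \code{trna_abundance}.
#' @param path Output path.
#' @export
write_trna_abundance_tsv <- function(abundance, path) {
  utils::write.table(as.data.frame(abundance), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
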