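#' Construct a validated CDS set
#'
#' Normalizes sequences (uppercase, RNA \code{U} to \code{T}), checks that
#' every CDS length is a multiple of three and that gene ids are unique.
#' Records containing ambiguity characters (anything outside \code{ACGT})
#' are dropped with a warning naming the offending ids; a length not
#' divisible by three is an error, since it indicates a broken annotation
#' rather than a sequencing artefact.
#'
#' @param sequences Named character vector of CDS sequences, or a
#'   \code{Biostrings::DNAStringSet}.  Names are gene ids.
#' @param organism Free-text label stored on the object.
#' @return An object of class \code{"transcript_set"}: a named character
#'   vector of clean CDS sequences with attribute \code{organism}.
#' @examples
#' ts <- transcript_set(c(g1 = "ATGGCGTAA"))
#' nchar(ts[["g1"]])
#' @export
transcript_set <- function(sequences, organism = "unspecified") {
  if (inherits(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (length(sequences) == 0L)
    return(structure(stats::setNames(character(0), character(0)),
                     class = "transcript_set", organism = organism))
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == ""))
    stop("every CDS sequence must be named by a gene id")
  if (anyDuplicated(names(sequences)))
    stop("duplicated gene ids: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  seqs <- toupper(sequences)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad_len <- nchar(seqs) %% 3L != 0L
  if (any(bad_len))
    stop("CDS length not divisible by 3 for gene(s): ",
         paste(names(seqs)[bad_len], collapse = ", "))
  ambiguous <- grepl("[^ACGT]", seqs)
  if (any(ambiguous)) {
    warning("dropping ", sum(ambiguous),
            " record(s) with ambiguity characters: ",
            paste(names(seqs)[ambiguous], collapse = ", "))
    seqs <- seqs[!ambiguous]
  }
  structure(seqs, class = "transcript_set", organism = organism)
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", length(x), "CDS record(s),",
      "organism:", attr(x, "organism"), "\n")
  if (length(x)) {
    show <- utils::head(seq_along(x), 3L)
    for (i in show)
      cat(" ", names(x)[i], " (", nchar(x[i]) %/% 3L, " codons)\n", sep = "")
    if (length(x) > 3L) cat("  ...\n")
  }
  invisible(x)
}

#' @export
`[.transcript_set` <- function(x, i, ...) {
  structure(NextMethod(), class = "transcript_set",
            organism = attr(x, "organism"))
}

#' Read a CDS FASTA file
#'
#' Multi-record, line-wrapped FASTA is read with
#' \code{Biostrings::readDNAStringSet}; only the first whitespace-delimited
#' token of each header is kept as the gene id.
#'
#' @param path Path to a FASTA file.
#' @inheritParams transcript_set
#' @return A \code{transcript_set}.
#' @export
read_cds_fasta <- function(path, organism = "unspecified") {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  transcript_set(x, organism = organism)
}

#' Write a transcript set to FASTA
#'
#' @param transcripts A \code{transcript_set}.
#' @param path Output path.
#' @export
write_cds_fasta <- function(transcripts, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(transcripts)), path)
  invisible(path)
}
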