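#' @importFrom Biostrings GENETIC_CODE DNAStringSet readDNAStringSet
#'   writeXStringSet trinucleotideFrequency
NULL

ALL_CODONS <- {
  b <- c("T", "C", "A", "G")
  as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0
  )))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Codon spaces
#'
#' The default analysis space contains the 60 sense codons obtained by
#' removing the three stop codons and the methionine codon \code{ATG} from
#' the 64 triplets: with single-copy initiator/elongator Met tRNAs sharing
#' one anticodon, \code{ATG} carries no usable adaptiveness signal and is
#' conventionally excluded.  \code{"sense61"} keeps \code{ATG} for generic
#' codon-usage work; stop codons are always excluded.
#'
#' @param space One of \code{"sense60"} (default) or \code{"sense61"}.
#' @return Character vector of codons (DNA alphabet, alphabetical order).
#' @examples
#' length(codon_space())          # 60
#' "ATG" %in% codon_space("sense61")
#' @export
codon_space <- function(space = c("sense60", "sense61")) {
  space <- match.arg(space)
  cods <- sort(setdiff(ALL_CODONS, STOP_CODONS))
  if (space == "sense60") cods <- setdiff(cods, "ATG")
  cods
}

#' Translate codons to one-letter amino acids
#'
#' @param codons Character vector of DNA codons.
#' @return Character vector of one-letter amino-acid codes (\code{"*"} for
#'   stops).
#' @export
codon_to_aa <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[toupper(codons)]
  unname(aa)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(ch)
    paste(rev(unname(DNA_COMPLEMENT[ch])), collapse = ""), character(1))
}

#' Anticodon decoded Watson-Crick by a codon (and vice versa)
#'
#' Anticodon positions 34-36 pair antiparallel with codon positions 3-1, so
#' the Watson-Crick anticodon of a codon is its reverse complement.
#'
#' @param codons Character vector of codons (or anticodons).
#' @return Character vector of reverse complements.
#' @export
wc_anticodon <- function(codons) revcomp(toupper(codons))
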