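#' Wobble base-pairing penalties
#'
#' Codon position 3 pairs with anticodon position 34; non-Watson-Crick
#' (wobble) pairings are penalized by a constant \code{s} in [0, 1], so a
#' decoder contributes \code{(1 - s)} times its abundance.  Defaults are
#' the classical tRNA-adaptation-index constants (Watson-Crick 0, G34:U
#' 0.41, I34:C 0.28, I34:A 0.9999, U34:G 0.68, lysidine:A 0.89), bundled as
#' an editable YAML file.  Modification rules rewrite the effective base at
#' position 34 before pairing: unmodified A34 is deaminated to inosine
#' (decoding U, C and A), and the bacterial Ile decoder with genomic
#' anticodon CAT carries lysidine at C34, switching it from AUG to AUA
#' decoding.
#'
#' @param file Path to a YAML penalty file; default is the bundled table.
#' @return List of class \code{"wobble_penalties"} with elements
#'   \code{pairing} (map: effective base 34 -> named numeric of codon-3
#'   bases to \code{s}) and \code{modifications} (list of rules with
#'   fields \code{base34} or \code{anticodon}+\code{isotype}, and
#'   \code{effective}).
#' @export
wobble_penalties <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "wobble_penalties.yaml",
                        package = "codonopt", mustWork = TRUE)
  cfg <- yaml::read_yaml(file)
  pairing <- lapply(cfg$pairing, function(p) unlist(p))
  s <- unlist(pairing)
  if (any(s < 0 | s > 1)) stop("penalties must lie in [0, 1]")
  for (b in c("A", "C", "G", "T")) {
    wc <- DNA_COMPLEMENT[[b]]
    if (!is.null(pairing[[b]]) && wc %in% names(pairing[[b]]) &&
        pairing[[b]][[wc]] != 0)
      stop("Watson-Crick pair ", b, ":", wc, " must have s = 0")
  }
  structure(list(pairing = pairing,
                 modifications = cfg$modifications),
            class = "wobble_penalties")
}

effective_base34 <- function(anticodon, isotype, rules) {
  base34 <- substr(anticodon, 1L, 1L)
  for (r in rules) {
    if (!is.null(r$anticodon)) {
      if (identical(r$anticodon, anticodon) &&
          (is.null(r$isotype) || identical(r$isotype, isotype)))
        return(r$effective)
    } else if (identical(r$base34, base34)) {
      return(r$effective)
    }
  }
  base34
}

#' Enumerate the decoders of each codon
#'
#' For every codon in the space, lists the anticodons that can decode it:
#' positions 1-2 of the codon must pair Watson-Crick with anticodon
#' positions 36-35, and position 3 pairs with the (modification-adjusted)
#' base 34 either Watson-Crick or by an allowed wobble, carrying the
#' penalty \code{s} of that pairing.  When isotypes are supplied, decoders
#' whose amino acid differs from the codon's are excluded — relevant for
#' inosine in split codon boxes, where unrestrained I34 pairing would
#' cross amino-acid boundaries.
#'
#' @param anticodons Character vector of anticodon 3-mers (DNA).
#' @param penalties A \code{\link{wobble_penalties}} object.
#' @param space Codon space (default the 60-codon space).
#' @param isotypes Optional character vector (one-letter amino acid per
#'   anticodon, recycled from names or parallel to \code{anticodons}).
#' @return Named list of class \code{"decoding_map"} over \code{space};
#'   each element a data frame with columns \code{anticodon}, \code{s}
#'   (possibly 0-row).
#' @examples
#' pen <- wobble_penalties()
#' m <- build_decoding_map("GTC", pen, isotypes = "D")
#' m[["GAC"]]   # Watson-Crick, s = 0
#' m[["GAT"]]   # G34:U wobble
#' @export
build_decoding_map <- function(anticodons, penalties = wobble_penalties(),
                               space = codon_space(), isotypes = NULL) {
  anticodons <- toupper(gsub("U", "T", anticodons))
  if (any(!grepl("^[ACGT]{3}$", anticodons)))
    stop("invalid anticodon(s): ",
         paste(anticodons[!grepl("^[ACGT]{3}$", anticodons)],
               collapse = ", "))
  if (!is.null(isotypes) && length(isotypes) != length(anticodons))
    stop("isotypes must parallel anticodons")
  space_aa <- codon_to_aa(space)
  map <- stats::setNames(
    rep(list(data.frame(anticodon = character(0), s = numeric(0))),
        length(space)), space)
  for (k in seq_along(anticodons)) {
    ac <- anticodons[k]
    iso <- if (is.null(isotypes)) NA_character_ else isotypes[k]
    eff <- effective_base34(ac, iso, penalties$modifications)
    pairs <- penalties$pairing[[eff]]
    if (is.null(pairs)) next
    c12 <- paste0(DNA_COMPLEMENT[[substr(ac, 3L, 3L)]],
                  DNA_COMPLEMENT[[substr(ac, 2L, 2L)]])
    for (b3 in names(pairs)) {
      codon <- paste0(c12, b3)
      i <- match(codon, space)
      if (is.na(i)) next
      if (!is.na(iso) && space_aa[i] != iso) next
      map[[i]] <- rbind(map[[i]],
                        data.frame(anticodon = ac, s = unname(pairs[[b3]])))
    }
  }
  structure(map, class = "decoding_map")
}

#' @export
print.decoding_map <- function(x, ...) {
  nd <- vapply(x, nrow, integer(1))
  cat("decoding_map:", length(x), "codons;",
      sum(nd == 0), "without decoder;",
      "mean decoders/codon:", round(mean(nd), 2), "\n")
  invisible(x)
}

#' Absolute adaptiveness W of each codon
#'
#' \code{W_i = sum_j (1 - s_ij) * abundance_j} over the decoders j of
#' codon i.  Codons with no decoder get \code{W_i = 0}.
#'
#' @param map A \code{\link{build_decoding_map}} result.
#' @param abundance A \code{\link{normalize_trna_counts}} table, or a named
#'   numeric vector of abundances per anticodon (e.g. all 1 for the
#'   gene-copy-number convention).
#' @return Named numeric vector \code{W} over the map's codon space.
#' @export
absolute_adaptiveness <- function(map, abundance) {
  stopifnot(inherits(map, "decoding_map"))
  if (is.data.frame(abundance)) {
    ab <- stats::setNames(abundance$abundance, abundance$anticodon)
  } else ab <- abundance
  used <- unique(unlist(lapply(map, function(d) d$anticodon)))
  missing <- setdiff(used, names(ab))
  if (length(missing))
    stop("no abundance for anticodon(s): ", paste(missing, collapse = ", "))
  vapply(map, function(d) {
    if (nrow(d) == 0L) return(0)
    sum((1 - d$s) * ab[d$anticodon])
  }, numeric(1))
}

#' Relative adaptiveness (TAc) from W
#'
#' Codons with non-zero W are normalized to the largest W; codons whose W
#' is exactly zero (no decoder in the pool) receive the geometric mean of
#' the non-zero normalized values, so they carry a typical, strictly
#' positive adaptiveness instead of an uninformative zero.
#'
#' @param W Named numeric vector from
#'   \code{\link{absolute_adaptiveness}}.
#' @return Data frame of class \code{"tac"} with columns \code{codon},
#'   \code{amino_acid}, \code{W}, \code{TAc}; attributes \code{W_max} and
#'   \code{W_mean} (the geometric-mean fallback on the normalized scale).
#' @examples
#' normalize_tac(c(GCA = 4, GCC = 1, GCG = 0))
#' @export
normalize_tac <- function(W) {
  if (any(W < 0)) stop("negative W")
  if (all(W == 0)) stop("all W values are zero")
  W_max <- max(W)
  rel <- W / W_max
  nz <- W != 0
  W_mean <- exp(mean(log(rel[nz])))
  tac <- ifelse(nz, rel, W_mean)
  df <- data.frame(codon = names(W), amino_acid = codon_to_aa(names(W)),
                   W = unname(W), TAc = unname(tac),
                   row.names = names(W))
  structure(df, class = c("tac", "data.frame"),
            W_max = W_max, W_mean = W_mean)
}

#' @export
print.tac <- function(x, ...) {
  cat("tac:", nrow(x), "codons; W_max =", format(attr(x, "W_max")),
      "\n top:", paste(utils::head(x$codon[order(-x$TAc)], 5),
                       collapse = " "),
      "\n bottom:", paste(utils::head(x$codon[order(x$TAc)], 3),
                          collapse = " "), "\n")
  invisible(x)
}

#' tRNA adaptability of codons from a measured tRNA pool
#'
#' Convenience wrapper: builds the wobble decoding map for the pool's
#' anticodons, sums penalty-weighted abundances into W, and normalizes to
#' TAc.
#'
#' @inheritParams absolute_adaptiveness
#' @inheritParams build_decoding_map
#' @param match_isotype Restrict decoders to the codon's amino acid when
#'   isotype information is available (default \code{TRUE}).
#' @return A \code{\link{normalize_tac}} table with an extra
#'   \code{n_decoders} column.
#' @export
compute_tac <- function(abundance, penalties = wobble_penalties(),
                        space = codon_space(), match_isotype = TRUE) {
  if (is.data.frame(abundance)) {
    anticodons <- abundance$anticodon
    isotypes <- if (match_isotype) abundance$amino_acid else NULL
  } else {
    anticodons <- names(abundance)
    isotypes <- NULL
  }
  map <- build_decoding_map(anticodons, penalties, space, isotypes)
  W <- absolute_adaptiveness(map, abundance)
  out <- normalize_tac(W)
  a <- attributes(out)[c("W_max", "W_mean")]
  out$n_decoders <- vapply(map, nrow, integer(1))[out$codon]
  out <- out[, c("codon", "amino_acid", "n_decoders", "W", "TAc")]
  class(out) <- c("tac", "data.frame")
  attr(out, "W_max") <- a$W_max
  attr(out, "W_mean") <- a$W_mean
  attr(out, "decoding_map") <- map
  out
}

#' Write a TAc table to TSV
#'
#' Columns: codon, amino_acid, n_decoders (when present), W, TAc.
#'
#' @param tac A \code{tac} table.
#' @param path Output path.
#' @export
write_tac_tsv <- function(tac, path) {
  utils::write.table(as.data.frame(tac), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
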