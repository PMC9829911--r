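#' Codon optimality: supply over demand
#'
#' \code{cOpt_i = log2(TAc_i / nCU_i)}: positive when the tRNA supply for
#' a codon exceeds its transcriptome demand (optimal), negative when
#' demand outstrips supply (suboptimal).
#'
#' @param tac A \code{\link{normalize_tac}}/\code{\link{compute_tac}}
#'   table.
#' @param ncu A \code{codon_usage} (normally the abundance-weighted
#'   flavor; the genomic flavor gives the demand-naive variant).
#' @param zero_floor Replacement for a zero relative usage before the
#'   ratio (default \code{1e-6}), applied with a warning; the log of a
#'   true zero is undefined.
#' @return Named numeric vector \code{cOpt} over the shared codon space.
#' @examples
#' tac <- normalize_tac(c(GCA = 8, GCC = 1))
#' ncu <- genomic_codon_usage(count_codons(
#'   transcript_set(c(g = "GCAGCC")), space = c("GCA", "GCC")))
#' codon_optimality(tac, ncu)
#' @export
codon_optimality <- function(tac, ncu, zero_floor = 1e-6) {
  stopifnot(inherits(tac, "tac"), inherits(ncu, "codon_usage"))
  if (!setequal(tac$codon, ncu$codon))
    stop("TAc and usage cover different codon spaces")
  rel <- stats::setNames(ncu$CU, ncu$codon)[tac$codon]
  if (any(rel == 0)) {
    warning(sum(rel == 0), " codon(s) with zero usage floored at ",
            zero_floor)
    rel[rel == 0] <- zero_floor
  }
  stats::setNames(log2(tac$TAc / rel), tac$codon)
}

#' mRNA optimality scores
#'
#' Aggregates per-codon optimality over each mRNA:
#' \code{mOpt_raw_j = sum_i C_ij cOpt_i}, divided by the gene's codon
#' count when \code{length_normalize} (the default, so the score is the
#' mean cOpt of the message and does not scale with gene length).  The
#' reported \code{mOpt} divides by the maximum absolute raw score, so
#' scores lie in [-1, 1] with the sign convention higher = more optimal.
#'
#' @param counts A \code{codon_counts} matrix.
#' @param cOpt Named numeric vector from \code{\link{codon_optimality}}.
#' @param length_normalize Divide each raw sum by the gene's counted
#'   codons (default \code{TRUE}).
#' @return Data frame of class \code{"mopt"} with columns
#'   \code{gene_id}, \code{mOpt_raw}, \code{mOpt}; attribute
#'   \code{normalization} records the convention.
#' @export
mrna_optimality <- function(counts, cOpt, length_normalize = TRUE) {
  stopifnot(inherits(counts, "codon_counts"))
  missing <- setdiff(rownames(counts)[rowSums(counts) > 0], names(cOpt))
  if (length(missing))
    stop("no cOpt for counted codon(s): ", paste(missing, collapse = ", "))
  totals <- colSums(counts)
  empty <- totals == 0
  if (any(empty)) {
    warning(sum(empty), " gene(s) with zero counted codons excluded: ",
            paste(utils::head(colnames(counts)[empty], 5), collapse = ", "))
    counts <- counts[, !empty, drop = FALSE]
    totals <- totals[!empty]
  }
  raw <- as.vector(cOpt[rownames(counts)] %*% counts)
  if (length_normalize) raw <- raw / totals
  scale <- max(abs(raw))
  m <- if (scale > 0) raw / scale else raw
  structure(data.frame(gene_id = colnames(counts), mOpt_raw = raw,
                       mOpt = m, row.names = colnames(counts)),
            class = c("mopt", "data.frame"),
            normalization = paste0(
              if (length_normalize) "mean cOpt per codon" else "raw cOpt sum",
              ", scaled by max |mOpt_raw|"))
}

#' @export
print.mopt <- function(x, ...) {
  cat("mopt:", nrow(x), "mRNAs;", attr(x, "normalization"), "\n")
  cat(sprintf(" mOpt range [%.3f, %.3f], median %.3f\n",
              min(x$mOpt), max(x$mOpt), stats::median(x$mOpt)))
  invisible(x)
}

#' Interquartile-range outlier fences for mRNA optimality
#'
#' Tukey fences at \code{Q1 - 1.5 IQR} and \code{Q3 + 1.5 IQR} (quartiles
#' by linear interpolation, \code{quantile} type 7); mRNAs strictly
#' outside are flagged.  Outlier counts are sensitive to the quartile
#' convention, hence it is fixed and recorded.
#'
#' @param mopt A \code{\link{mrna_optimality}} table, or a named numeric
#'   vector of scores.
#' @return List of class \code{"mopt_outliers"}: \code{cutoff_low},
#'   \code{cutoff_high}, \code{outliers_low}, \code{outliers_high}
#'   (character vectors of gene ids).
#' @examples
#' flag_outliers(c(a = 1, b = 2, c = 3, d = 4, e = 5))
#' @export
flag_outliers <- function(mopt) {
  v <- if (is.data.frame(mopt)) stats::setNames(mopt$mOpt, mopt$gene_id)
       else mopt
  if (length(v) < 4) stop("need at least 4 values for quartile fences")
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  structure(list(cutoff_low = lo, cutoff_high = hi,
                 outliers_low = names(v)[v < lo],
                 outliers_high = names(v)[v > hi]),
            class = "mopt_outliers")
}

#' @export
print.mopt_outliers <- function(x, ...) {
  cat(sprintf("fences [%.4f, %.4f]; %d low / %d high outlier(s)\n",
              x$cutoff_low, x$cutoff_high,
              length(x$outliers_low), length(x$outliers_high)))
  invisible(x)
}

#' Fit the codon/mRNA optimality model
#'
#' The one-stop estimator: from a CDS set, a measured tRNA pool and an
#' RNA-seq count table it computes tRNA adaptability (TAc) with wobble
#' penalties, genomic and demand-weighted codon usage, per-codon
#' optimality \code{cOpt = log2(TAc / nCU)}, per-mRNA optimality
#' \code{mOpt}, and IQR outlier calls.
#'
#' @param transcripts A \code{\link{transcript_set}}.
#' @param trna Either an \code{\link{anticodon_count_table}} (raw read
#'   counts) or a \code{trna_abundance} table.
#' @param rna_counts Named numeric vector or \code{expression_table} of
#'   RNA-seq counts; \code{NULL} uses genomic usage as the demand proxy.
#' @param penalties A \code{\link{wobble_penalties}} object.
#' @param space Codon space (default 60 sense codons, no \code{ATG}).
#' @param pseudocount CPM pseudocount for both tRNA and RNA normalization.
#' @param length_normalize Passed to \code{\link{mrna_optimality}}.
#' @return Object of class \code{"codopt"} with components
#'   \code{tac}, \code{cu}, \code{ncu}, \code{cOpt}, \code{mopt},
#'   \code{outliers}, \code{counts}, \code{expr}, \code{settings}.
#' @seealso \code{\link{predict.codopt}}, \code{\link{summary.codopt}}
#' @export
fit_optimality <- function(transcripts, trna, rna_counts = NULL,
                           penalties = wobble_penalties(),
                           space = codon_space(), pseudocount = 1,
                           length_normalize = TRUE) {
  abundance <- if (inherits(trna, "trna_abundance")) trna
               else normalize_trna_counts(trna, pseudocount)
  tac <- compute_tac(abundance, penalties, space)
  counts <- count_codons(transcripts, space)
  cu <- genomic_codon_usage(counts)
  expr <- NULL
  if (!is.null(rna_counts)) {
    expr <- if (inherits(rna_counts, "expression_table")) rna_counts
            else normalize_rna_counts(rna_counts, pseudocount)
    ncu <- abundance_weighted_usage(counts, expr)
  } else ncu <- cu
  cOpt <- codon_optimality(tac, ncu)
  mopt <- mrna_optimality(counts, cOpt, length_normalize)
  structure(list(tac = tac, cu = cu, ncu = ncu, cOpt = cOpt,
                 mopt = mopt, outliers = flag_outliers(mopt),
                 counts = counts, expr = expr, abundance = abundance,
                 settings = list(space = space, pseudocount = pseudocount,
                                 length_normalize = length_normalize,
                                 demand = if (is.null(rna_counts))
                                   "genomic" else "abundance-weighted")),
            class = "codopt")
}

#' @export
print.codopt <- function(x, ...) {
  cat("Codon/mRNA optimality fit\n")
  cat(" ", length(x$cOpt), " codons, ", nrow(x$mopt), " mRNAs, demand: ",
      x$settings$demand, "\n", sep = "")
  cat(" ", sum(x$cOpt > 0), " optimal codons (cOpt > 0); ",
      length(x$outliers$outliers_low), " low-mOpt outlier(s)\n", sep = "")
  invisible(x)
}

#' @method summary codopt
#' @export
summary.codopt <- function(object, ...) {
  cmp <- compare_usage(object$tac, object$cu)
  out <- list(n_codons = length(object$cOpt),
              n_mrnas = nrow(object$mopt),
              n_optimal = sum(object$cOpt > 0),
              n_below_minus2 = sum(object$cOpt < -2),
              lowest_codon = names(which.min(object$cOpt)),
              tac_vs_cu = cmp,
              outliers = object$outliers,
              mopt_range = range(object$mopt$mOpt))
  class(out) <- "summary.codopt"
  out
}

#' @export
print.summary.codopt <- function(x, ...) {
  cat("Codon/mRNA optimality summary\n")
  cat(sprintf("  %d / %d codons optimal (cOpt > 0); %d below -2; lowest: %s\n",
              x$n_optimal, x$n_codons, x$n_below_minus2, x$lowest_codon))
  cat(sprintf("  TAc vs genomic CU: Spearman rho = %.3f (p = %.2g)\n",
              x$tac_vs_cu$estimate, x$tac_vs_cu$p.value))
  cat(sprintf("  mOpt in [%.3f, %.3f]; low outliers: %d, high: %d\n",
              x$mopt_range[1], x$mopt_range[2],
              length(x$outliers$outliers_low),
              length(x$outliers$outliers_high)))
  invisible(x)
}

#' @method coef codopt
#' @export
coef.codopt <- function(object, ...) object$cOpt

#' Score new mRNAs against a fitted optimality model
#'
#' @param object A \code{\link{fit_optimality}} fit.
#' @param newdata A \code{transcript_set} of CDS to score.
#' @param ... Unused.
#' @return Named numeric vector of mOpt scores on the fit's scale (raw
#'   scores divided by the fit's maximum absolute raw score).
#' @export
predict.codopt <- function(object, newdata, ...) {
  counts <- count_codons(newdata, object$settings$space)
  raw <- as.vector(object$cOpt[rownames(counts)] %*% counts)
  if (object$settings$length_normalize) raw <- raw / colSums(counts)
  scale <- max(abs(object$mopt$mOpt_raw))
  stats::setNames(raw / scale, colnames(counts))
}

#' @method plot codopt
#' @export
plot.codopt <- function(x, which = c("copt", "tac_vs_cu"), ...) {
  which <- match.arg(which)
  if (which == "copt") {
    v <- sort(x$cOpt)
    graphics::barplot(v, las = 2, cex.names = 0.5,
                      col = ifelse(v > 0, "steelblue", "goldenrod"),
                      ylab = "cOpt = log2(TAc / nCU)", ...)
  } else {
    graphics::plot(x$cu$cu, x$tac[x$cu$codon, "TAc"],
                   xlab = "genomic codon usage", ylab = "TAc", ...)
  }
  invisible(x)
}

#' Write the per-codon and per-gene optimality tables
#'
#' @param fit A \code{codopt} fit.
#' @param codon_path,gene_path,json_path Output paths (any may be
#'   \code{NULL} to skip).
#' @export
write_optimality_tsv <- function(fit, codon_path = NULL, gene_path = NULL,
                                 json_path = NULL) {
  if (!is.null(codon_path)) {
    ncu_rel <- stats::setNames(fit$ncu$CU, fit$ncu$codon)
    df <- data.frame(codon = fit$tac$codon,
                     amino_acid = fit$tac$amino_acid,
                     TAc = fit$tac$TAc,
                     nCU = unname(ncu_rel[fit$tac$codon]),
                     cOpt = unname(fit$cOpt[fit$tac$codon]),
                     optimal = fit$cOpt[fit$tac$codon] > 0)
    utils::write.table(df, codon_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(gene_path)) {
    out <- fit$mopt
    out$outlier <- ifelse(out$gene_id %in% fit$outliers$outliers_low, "low",
                   ifelse(out$gene_id %in% fit$outliers$outliers_high,
                          "high", "none"))
    utils::write.table(out, gene_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path))
    jsonlite::write_json(list(cutoff_low = fit$outliers$cutoff_low,
                              cutoff_high = fit$outliers$cutoff_high,
                              normalization = attr(fit$mopt,
                                                   "normalization")),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(fit)
}
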