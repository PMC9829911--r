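rank_cor <- function(x, y) {
  shared <- intersect(names(x), names(y))
  ct <- stats::cor.test(x[shared], y[shared], method = "spearman",
                        exact = FALSE)
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       n = length(shared))
}

manifest_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Run the full codon-optimality pipeline
#'
#' Composes the stages end to end: tRNA quantification, wobble-penalized
#' TAc, codon counting, demand-weighted usage, codon/mRNA optimality with
#' outlier calling, and (when footprint data are present) P-site offset
#' estimation, A-site pause scores and naive translation efficiency,
#' plus the standard rank-correlation reports (TAc vs genomic usage,
#' mOpt vs abundance, mOpt vs TE, pause vs TAc).
#'
#' @param config Either a YAML file path or a list with elements:
#'   \describe{
#'     \item{simulate}{logical; generate all inputs synthetically.}
#'     \item{sim}{list of \code{\link{sim_config}} arguments (simulate
#'       mode).}
#'     \item{inputs}{list of paths \code{cds_fasta}, \code{trna_counts},
#'       \code{rna_counts}, optionally \code{ribo_reads} (input mode).}
#'     \item{options}{list: \code{pseudocount}, \code{length_normalize},
#'       \code{genomic_mean}, \code{asite_shift}, \code{filter} (list
#'       with \code{min_len_nt}, \code{skip_5p_nt},
#'       \code{min_mean_cov}).}
#'   }
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as TSV/JSON together with a manifest recording the
#'   configuration hash and chosen conventions.
#' @return List of class \code{"codonopt_run"}: \code{fit} (the
#'   \code{codopt} object), \code{offsets}, \code{pause}, \code{te},
#'   \code{reports}, \code{sim} (generator outputs in simulate mode),
#'   \code{manifest}.
#' @examples
#' \donttest{
#' run <- run_pipeline(list(simulate = TRUE,
#'                          sim = list(seed = 7, n_genes = 60)))
#' run$reports$tac_vs_cu$estimate
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  opts <- utils::modifyList(
    list(pseudocount = 1, length_normalize = TRUE,
         genomic_mean = "pooled", asite_shift = 3L,
         pause_skip_codons = 7L,
         filter = list(min_len_nt = 100, skip_5p_nt = 21,
                       min_mean_cov = 40)),
    config$options %||% list())
  sim_out <- NULL
  ribo <- NULL
  if (isTRUE(config$simulate)) {
    scfg <- do.call(sim_config, config$sim %||% list())
    pool <- simulate_trna_pool(scfg,
                               profile = config$trna_profile %||%
                                 "loguniform")
    txome <- simulate_transcriptome(scfg)
    ribo_sim <- simulate_ribo_profile(txome$transcripts, scfg)
    transcripts <- txome$transcripts
    rna_counts <- txome$rna_counts
    reads <- ribo_sim$reads
    ribo_counts <- ribo_sim$ribo_counts
    sim_out <- list(config = scfg, pool = pool, transcriptome = txome,
                    ribo = ribo_sim)
  } else {
    inp <- config$inputs
    if (is.null(inp$cds_fasta) || is.null(inp$trna_counts))
      stop("inputs must name at least cds_fasta and trna_counts")
    for (p in unlist(inp)) if (!file.exists(p)) stop("missing input: ", p)
    transcripts <- read_cds_fasta(inp$cds_fasta)
    pool <- read_anticodon_counts(inp$trna_counts)
    rna_counts <- if (!is.null(inp$rna_counts)) {
      df <- utils::read.delim(inp$rna_counts, stringsAsFactors = FALSE)
      stats::setNames(df$count, df$gene_id)
    }
    reads <- if (!is.null(inp$ribo_reads)) read_ribo_reads(inp$ribo_reads)
    ribo_counts <- if (!is.null(reads))
      tapply(reads$count, reads$gene_id, sum)
  }
  fit <- fit_optimality(transcripts, pool, rna_counts,
                        pseudocount = opts$pseudocount,
                        length_normalize = opts$length_normalize)
  offsets <- pause <- te <- NULL
  if (!is.null(reads)) {
    offsets <- metagene_psite_offsets(reads)
    profile <- build_ribo_profile(reads, offsets,
                                  stats::setNames(nchar(transcripts),
                                                  names(transcripts)),
                                  asite_shift = opts$asite_shift)
    filtered <- suppressWarnings(
      filter_genes(profile, opts$filter$min_len_nt,
                   opts$filter$skip_5p_nt, opts$filter$min_mean_cov))
    if (length(filtered$density) == 0L) {
      warning("no genes pass the coverage filter; scoring unfiltered ",
              "profile")
      filtered <- profile
    }
    pause <- pause_scores(filtered, transcripts,
                          genomic_mean = opts$genomic_mean,
                          skip_5p_codons = opts$pause_skip_codons)
    if (!is.null(rna_counts))
      te <- translation_efficiency(ribo_counts, rna_counts,
                                   opts$pseudocount)
  }
  mopt_v <- stats::setNames(fit$mopt$mOpt, fit$mopt$gene_id)
  reports <- list(tac_vs_cu = rank_cor(
    stats::setNames(fit$tac$TAc, fit$tac$codon),
    stats::setNames(fit$cu$cu, fit$cu$codon)))
  if (!is.null(fit$expr))
    reports$mopt_vs_abundance <- rank_cor(
      mopt_v, stats::setNames(fit$expr$a, fit$expr$gene_id))
  if (!is.null(te)) reports$mopt_vs_te <- rank_cor(mopt_v, te)
  if (!is.null(pause))
    reports$pause_vs_tac <- rank_cor(
      pause$genomic, stats::setNames(fit$tac$TAc, fit$tac$codon))
  manifest <- list(
    config_hash = manifest_hash(config),
    seed = if (!is.null(sim_out)) sim_out$config$seed,
    conventions = list(
      mopt_normalization = attr(fit$mopt, "normalization"),
      asite_shift = opts$asite_shift,
      genomic_pause_mean = opts$genomic_mean,
      codon_space = length(fit$settings$space)),
    package_version = as.character(utils::packageVersion("codonopt")))
  run <- structure(list(fit = fit, offsets = offsets, pause = pause,
                        te = te, reports = reports, sim = sim_out,
                        manifest = manifest),
                   class = "codonopt_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.codonopt_run <- function(x, ...) {
  cat("codonopt pipeline run (config", x$manifest$config_hash, ")\n")
  print(x$fit)
  for (nm in names(x$reports))
    cat(sprintf("  %-18s rho = %+.3f (p = %.2g, n = %d)\n", nm,
                x$reports[[nm]]$estimate, x$reports[[nm]]$p.value,
                x$reports[[nm]]$n))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_tac_tsv(run$fit$tac, p("tac.tsv"))
  write_usage_tsv(run$fit$cu, p("genomic_usage.tsv"))
  write_usage_tsv(run$fit$ncu, p("ncu.tsv"))
  write_optimality_tsv(run$fit, p("codon_optimality.tsv"),
                       p("mrna_optimality.tsv"), p("outlier_cutoffs.json"))
  if (!is.null(run$pause))
    write_pause_tsv(run$pause, p("pause_codon.tsv"), p("pause_aa.tsv"),
                    run$offsets, p("psite_offsets.json"))
  if (!is.null(run$te))
    utils::write.table(data.frame(gene_id = names(run$te),
                                  log2_te = unname(run$te)),
                       p("translation_efficiency.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(run$sim))
    jsonlite::write_json(
      list(seed = run$sim$config$seed,
           trna_truth = attr(run$sim$pool, "ground_truth"),
           offsets_truth = as.list(run$sim$ribo$truth$offsets)),
      p("simulation_truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  reports <- lapply(run$reports, function(r)
    list(spearman_rho = r$estimate, p_value = r$p.value, n = r$n))
  jsonlite::write_json(reports, p("reports.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
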