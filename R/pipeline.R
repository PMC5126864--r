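#' Pipeline configuration
#'
#' Aggregates the analysis thresholds with their study defaults: SNP site
#' depth minimum 15, error rate 0.01 with tail bound 1e-4, inclusion filter
#' of 12 replicated genotypes, cpm filter 1 cpm in 10 samples, FDR 0.20, MAF
#' 0.30, reference-bias strata at 0.45/0.55, and the seed. `simulation` holds
#' a [simulation_config()] used when the pipeline generates its own input.
#'
#' @param simulation a [simulation_config()].
#' @param seed master seed for all randomized stages.
#' @param min_depth,error_rate,alpha SNP filter parameters.
#' @param min_replicated_genotypes ASE inclusion threshold.
#' @param min_cpm,min_cpm_samples expression filter.
#' @param fdr_threshold ASE / DE significance level.
#' @param maf_threshold minor-allele-frequency cutoff.
#' @param bias_lo,bias_hi reference-bias strata boundaries.
#' @param ci_method reported binomial CI method.
#' @param lrt_null ASE LRT reference (`"chisq1"` or `"mixture"`).
#' @param conflict_rule read-conflict rule (`"drop_read"` or `"drop_snp"`).
#' @param nagq quadrature nodes per dimension.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(), seed = 1L,
                            min_depth = 15, error_rate = 0.01, alpha = 1e-4,
                            min_replicated_genotypes = 12, min_cpm = 1,
                            min_cpm_samples = 10, fdr_threshold = 0.2,
                            maf_threshold = 0.3, bias_lo = 0.45,
                            bias_hi = 0.55, ci_method = "wilson",
                            lrt_null = "chisq1",
                            conflict_rule = "drop_read", nagq = 9) {
  stopifnot(min_depth >= 1, error_rate > 0, error_rate < 1, alpha > 0,
            alpha < 1, fdr_threshold > 0, fdr_threshold <= 1,
            maf_threshold > 0, maf_threshold <= 0.5,
            bias_lo < bias_hi, bias_lo > 0, bias_hi < 1, nagq >= 1)
  cfg <- list(simulation = simulation, seed = as.integer(seed),
              min_depth = min_depth, error_rate = error_rate, alpha = alpha,
              min_replicated_genotypes = min_replicated_genotypes,
              min_cpm = min_cpm, min_cpm_samples = min_cpm_samples,
              fdr_threshold = fdr_threshold, maf_threshold = maf_threshold,
              bias_lo = bias_lo, bias_hi = bias_hi, ci_method = ci_method,
              lrt_null = lrt_null, conflict_rule = conflict_rule,
              nagq = nagq)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full ASE + clinal pipeline on simulated input
#'
#' Executes the stages simulate -> reference-bias summary -> ASE testing ->
#' allele grouping (significant genes) -> allele frequencies -> total
#' expression + cpm filter -> latitudinal DE per continent -> cross-continent
#' concordance -> latitudinal ASE differences -> cross-continent ASE
#' correlation -> ASE enrichment -> major/minor and ASE-vs-total summaries.
#' Every stage's output can be written as TSV/JSON under `outdir` together
#' with a manifest recording stage names, parameters and the seed. Rerunning
#' with the same config reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (`NULL` skips writing).
#' @param quiet suppress progress messages.
#' @return invisible result bundle (list of all stage outputs plus
#'   `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  stages <- character(0)
  t0 <- Sys.time()

  say("stage simulate")
  sim <- simulate_ase_dataset(config$simulation, seed = config$seed)
  stages <- c(stages, "simulate")

  say("stage reference_bias")
  bias <- reference_bias_summary(sim$counts, config$bias_lo, config$bias_hi)
  stages <- c(stages, "reference_bias")

  say("stage ase_test")
  ase <- ase_test_table(sim$counts, fdr_threshold = config$fdr_threshold,
                        min_replicated_genotypes =
                          config$min_replicated_genotypes,
                        nagq = config$nagq, null_dist = config$lrt_null)
  stages <- c(stages, "ase_test")

  sig_genes <- ase$gene[ase$significant]
  say("stage grouping (", length(sig_genes), " significant genes)")
  grouping <- if (length(sig_genes))
    group_alleles(sim$counts, genes = sig_genes, nagq = config$nagq)
  else list(summary = tibble::tibble(), line_calls = tibble::tibble())
  stages <- c(stages, "grouping")

  freqs <- if (nrow(grouping$line_calls))
    allele_frequencies(grouping$line_calls, sim$metadata)
  else list(per_population = tibble::tibble(), per_gene = tibble::tibble())
  stages <- c(stages, "allele_frequencies")

  say("stage total_expression")
  expr <- simulate_total_expression(config$simulation, sim$truth,
                                    sim$metadata, seed = config$seed + 1L)
  filt <- cpm_and_filter(expr, config$min_cpm, config$min_cpm_samples)
  stages <- c(stages, "total_expression")

  say("stage latitudinal_de")
  continents <- unique(sim$metadata$continent)
  de <- lapply(continents, function(cc)
    latitudinal_de_test(filt$cpm, sim$metadata, cc))
  names(de) <- continents
  conc <- if (length(de) >= 2)
    sign_concordance(de[[1]], de[[2]], config$fdr_threshold)
  else NULL
  stages <- c(stages, "latitudinal_de")

  say("stage latitudinal_ase")
  lat_ase <- if (length(sig_genes))
    latitudinal_ase_differences(sim$counts, genes = sig_genes,
                                nagq = config$nagq)
  else tibble::tibble()
  ase_corr <- NULL
  if (nrow(lat_ase) && length(continents) >= 2) {
    wide <- tidyr::pivot_wider(lat_ase, id_cols = "gene",
                               names_from = "continent",
                               values_from = "ase_diff")
    ok <- complete.cases(wide)
    if (sum(ok) >= 3)
      ase_corr <- spearman_correlation(wide[[continents[1]]][ok],
                                       wide[[continents[2]]][ok])
  }
  stages <- c(stages, "latitudinal_ase")

  say("stage enrichment")
  lat_genes <- .parallel_lat_genes(de, config)
  universe <- intersect(ase$gene, rownames(filt$cpm))
  enrich <- if (length(universe))
    ase_enrichment(intersect(lat_genes, universe),
                   intersect(sig_genes, universe), universe)
  else NULL
  stages <- c(stages, "enrichment")

  mm <- if (nrow(grouping$line_calls))
    major_minor_expression(grouping$line_calls, freqs$per_gene, filt$cpm,
                           sim$metadata, config$maf_threshold)
  else NULL
  at <- if (nrow(grouping$line_calls))
    ase_total_correlation(grouping, filt$cpm, sim$metadata)
  else NULL
  stages <- c(stages, "effects")

  manifest <- list(
    package = "clinase",
    version = as.character(utils::packageVersion("clinase")),
    seed = config$seed, stages = stages,
    parameters = unclass(config[setdiff(names(config), "simulation")]),
    simulation = unclass(config$simulation),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  bundle <- list(simulation = sim, bias = bias, ase = ase,
                 grouping = grouping, frequencies = freqs,
                 expression = expr, cpm = filt, de = de, concordance = conc,
                 latitudinal_ase = lat_ase, ase_correlation = ase_corr,
                 enrichment = enrich, major_minor = mm,
                 ase_total = at, manifest = manifest)

  if (!is.null(outdir)) .write_bundle(bundle, outdir)
  invisible(bundle)
}

.parallel_lat_genes <- function(de, config) {
  # latitudinal differentiation: p < 0.05 on >= 1 continent and the same
  # direction of change on both (the definition used for the enrichment)
  if (length(de) < 2) return(character(0))
  both <- dplyr::inner_join(de[[1]], de[[2]], by = "gene",
                            suffix = c("_A", "_B"))
  sel <- (both$p_A < 0.05 | both$p_B < 0.05) &
    sign(both$log2_fold_A) == sign(both$log2_fold_B) &
    both$log2_fold_A != 0
  both$gene[sel & !is.na(sel)]
}

.write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) if (!is.null(x) && is.data.frame(x) && nrow(x))
    readr::write_tsv(x, file.path(outdir, name))
  w(bundle$simulation$counts, "allele_counts.tsv")
  w(bundle$simulation$metadata, "metadata.tsv")
  w(bundle$simulation$truth$genes, "truth_genes.tsv")
  w(bundle$ase, "ase_tests.tsv")
  w(bundle$grouping$summary, "grouping_summary.tsv")
  w(bundle$grouping$line_calls, "line_calls.tsv")
  w(bundle$frequencies$per_gene, "allele_frequencies.tsv")
  w(bundle$latitudinal_ase, "latitudinal_ase.tsv")
  for (cc in names(bundle$de))
    w(bundle$de[[cc]], paste0("latitudinal_de_", cc, ".tsv"))
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
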