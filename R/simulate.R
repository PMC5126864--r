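#' Configuration for the synthetic study-design generator
#'
#' Encodes the sampling design the generator emulates: populations are the
#' cross of continents and latitude classes (temperate / tropical), each
#' population contributes `genotypes_per_population` wild haploid genomes
#' crossed to the reference strain, and a subset of genotypes per population
#' has a biological replicate. Allele counts are generated from the same
#' binomial logit mixed model the analysis fits:
#' \deqn{wild \sim Binomial(depth, logit^{-1}(baseline + \delta \cdot carrier
#'   + u_{genotype} + v_{replicate} - bias))}
#' where `delta` is the per-gene cis-regulatory effect of the non-reference
#' (alternate) CRE allele, `carrier` indicates genotypes carrying that allele
#' (drawn from the population's allele frequency), and `bias` is an additive
#' logit shift toward the reference allele emulating residual mapping bias.
#'
#' @param n_genes number of genes to simulate.
#' @param n_continents,n_latitudes_per_continent design cross (defaults 2 x 2).
#' @param genotypes_per_population wild lines per population (default 13).
#' @param replicated_genotypes_per_population lines per population with a
#'   biological replicate (default 4).
#' @param depth_mean,depth_dispersion negative-binomial mean and size of the
#'   per-(gene, sample) allele-informative read depth.
#' @param baseline_logit logit-scale mean of the wild/reference ratio
#'   (0 = balanced).
#' @param cre_effect_sd SD of the per-gene CRE effect `delta` (logit scale).
#' @param cre_effect_fixed optional fixed `delta` applied to every gene
#'   (overrides the normal draw; used for planted-effect simulations).
#' @param cre_freq_by_population alternate-CRE-allele frequency per
#'   population: `NULL` (0.5 everywhere), a single value, or a named vector
#'   keyed by population id or by latitude class (`"temperate"`,
#'   `"tropical"`), which allows latitude-structured frequencies.
#' @param cre_freq_beta optional `c(shape1, shape2)` of a Beta distribution
#'   from which each gene draws its own alternate-allele frequency (shared
#'   across populations), emulating a realistic per-gene allele-frequency
#'   spectrum; mutually exclusive with `cre_freq_by_population`.
#' @param rare_allele_low_prob optional probability that a gene's CRE effect
#'   sign is oriented so the minority allele is the lower-expressed one
#'   (emulating low-frequency expression-reducing variants); `NULL` (default)
#'   leaves effect signs independent of frequency.
#' @param genotype_sd,replicate_sd residual genotype-level and replicate-level
#'   logit SDs (`sigma_g`, `sigma_r`).
#' @param mapping_bias_logit additive logit shift toward the reference allele;
#'   the default 0.004 reproduces a mean reference fraction of about 50.1%.
#' @param total_expression_coupling multiplicative effect of carrying the
#'   higher-expressed CRE allele on expected total counts (1 = no coupling).
#' @param error_rate per-base sequencing error probability for pileup
#'   simulation.
#' @param seed default master seed recorded in the config (functions take an
#'   explicit `seed` argument which wins).
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 100,
                              n_continents = 2,
                              n_latitudes_per_continent = 2,
                              genotypes_per_population = 13,
                              replicated_genotypes_per_population = 4,
                              depth_mean = 100, depth_dispersion = 5,
                              baseline_logit = 0,
                              cre_effect_sd = 0.5,
                              cre_effect_fixed = NULL,
                              cre_freq_by_population = NULL,
                              cre_freq_beta = NULL,
                              rare_allele_low_prob = NULL,
                              genotype_sd = 0.1, replicate_sd = 0.2,
                              mapping_bias_logit = 0.004,
                              total_expression_coupling = 1.3,
                              error_rate = 0.01,
                              seed = 1L) {
  cfg <- list(n_genes = n_genes, n_continents = n_continents,
              n_latitudes_per_continent = n_latitudes_per_continent,
              genotypes_per_population = genotypes_per_population,
              replicated_genotypes_per_population =
                replicated_genotypes_per_population,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              baseline_logit = baseline_logit, cre_effect_sd = cre_effect_sd,
              cre_effect_fixed = cre_effect_fixed,
              cre_freq_by_population = cre_freq_by_population,
              cre_freq_beta = cre_freq_beta,
              rare_allele_low_prob = rare_allele_low_prob,
              genotype_sd = genotype_sd, replicate_sd = replicate_sd,
              mapping_bias_logit = mapping_bias_logit,
              total_expression_coupling = total_expression_coupling,
              error_rate = error_rate, seed = as.integer(seed))
  counts <- c("n_genes", "n_continents", "n_latitudes_per_continent",
              "genotypes_per_population")
  for (f in counts)
    if (cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop(f, " must be a positive integer")
  if (cfg$replicated_genotypes_per_population < 0 ||
      cfg$replicated_genotypes_per_population > cfg$genotypes_per_population)
    stop("replicated genotypes must be between 0 and genotypes per population")
  for (f in c("cre_effect_sd", "genotype_sd", "replicate_sd",
              "depth_mean", "depth_dispersion"))
    if (cfg[[f]] < 0) stop(f, " must be non-negative")
  fr <- cfg$cre_freq_by_population
  if (!is.null(fr) && (any(fr < 0) || any(fr > 1)))
    stop("cre_freq_by_population values must lie in [0, 1]")
  if (!is.null(cfg$cre_freq_beta)) {
    if (!is.null(fr))
      stop("cre_freq_by_population and cre_freq_beta are mutually exclusive")
    if (length(cfg$cre_freq_beta) != 2 || any(cfg$cre_freq_beta <= 0))
      stop("cre_freq_beta must be two positive shape parameters")
  }
  if (!is.null(cfg$rare_allele_low_prob) &&
      (cfg$rare_allele_low_prob < 0 || cfg$rare_allele_low_prob > 1))
    stop("rare_allele_low_prob must lie in [0, 1]")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    stop("error_rate must lie in [0, 1)")
  if (cfg$total_expression_coupling <= 0)
    stop("total_expression_coupling must be positive")
  class(cfg) <- "sim_config"
  cfg
}

.sim_populations <- function(cfg) {
  lat_names <- c("temperate", "tropical")
  lats <- if (cfg$n_latitudes_per_continent <= 2)
    lat_names[seq_len(cfg$n_latitudes_per_continent)]
  else paste0("lat", seq_len(cfg$n_latitudes_per_continent))
  expand.grid(latitude = lats,
              continent = paste0("C", seq_len(cfg$n_continents)),
              stringsAsFactors = FALSE)[, c("continent", "latitude")]
}

#' Sample metadata implied by a simulation config
#'
#' @param config a [simulation_config()].
#' @return tibble: `sample`, `genotype`, `replicate`, `population`,
#'   `latitude`, `continent`. Replicated genotypes contribute two samples.
#' @export
simulate_metadata <- function(config) {
  pops <- .sim_populations(config)
  rows <- lapply(seq_len(nrow(pops)), function(i) {
    pop <- paste(pops$continent[i], pops$latitude[i], sep = "_")
    geno <- sprintf("%s_g%02d", pop, seq_len(config$genotypes_per_population))
    nrep <- config$replicated_genotypes_per_population
    reps <- lapply(seq_along(geno), function(j) {
      r <- if (j <= nrep) c("r1", "r2") else "r1"
      tibble::tibble(genotype = geno[j], replicate = r)
    })
    out <- dplyr::bind_rows(reps)
    out$population <- pop
    out$latitude <- pops$latitude[i]
    out$continent <- pops$continent[i]
    out
  })
  md <- dplyr::bind_rows(rows)
  md$sample <- paste(md$genotype, md$replicate, sep = "_")
  md[, c("sample", "genotype", "replicate", "population", "latitude",
         "continent")]
}

.pop_freqs <- function(cfg, populations, latitudes) {
  fr <- cfg$cre_freq_by_population
  if (is.null(fr)) return(setNames(rep(0.5, length(populations)), populations))
  if (length(fr) == 1 && is.null(names(fr)))
    return(setNames(rep(fr, length(populations)), populations))
  if (!is.null(names(fr)) && all(populations %in% names(fr)))
    return(setNames(fr[populations], populations))
  if (!is.null(names(fr)) && all(latitudes %in% names(fr)))
    return(setNames(fr[latitudes], populations))
  stop("cre_freq_by_population must be unnamed length-1, or named by ",
       "population id or latitude class")
}

.gene_seed <- function(seed, j) as.integer((as.numeric(seed) + 7919 * j) %%
                                             2147483647)

#' Simulate an allele-specific-expression dataset with ground truth
#'
#' Draws, for every gene, a cis-regulatory effect `delta ~ N(0,
#' cre_effect_sd)`, per-genotype carrier status of the alternate CRE allele
#' from the population's allele frequency (the wild chromosome is haploid in
#' the cross design), genotype and replicate logit noise, a negative-binomial
#' read depth per (gene, sample), and binomial wild-allele counts under the
#' logit model described in [simulation_config()]. Replicated genotypes share
#' their genotype-level effect but get independent replicate effects.
#' Identical `(config, seed)` give identical output. Rows with zero simulated
#' depth are omitted (sparse convention).
#'
#' @param config a [simulation_config()].
#' @param seed integer master seed; per-gene streams are derived
#'   deterministically from `(seed, gene index)`.
#' @return list of class `ase_simulation` with `counts` (gene, sample,
#'   genotype, replicate, population, continent, latitude, wild_count,
#'   ref_count), `metadata`, and `truth` (per-gene `delta`, per-genotype
#'   carrier status, per-(gene, population) alternate-allele frequency,
#'   `sigma_g`, `sigma_r`).
#' @export
simulate_ase_dataset <- function(config, seed = config$seed) {
  md <- simulate_metadata(config)
  pops <- unique(md[, c("population", "latitude")])
  freqs <- .pop_freqs(config, pops$population, pops$latitude)
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  geno_md <- unique(md[, c("genotype", "population")])

  counts <- vector("list", config$n_genes)
  deltas <- numeric(config$n_genes)
  carriers <- vector("list", config$n_genes)
  freq_rows <- vector("list", config$n_genes)
  for (j in seq_len(config$n_genes)) {
    set.seed(.gene_seed(seed, j))
    delta <- if (!is.null(config$cre_effect_fixed)) config$cre_effect_fixed
    else rnorm(1, 0, config$cre_effect_sd)
    gene_freqs <- if (!is.null(config$cre_freq_beta))
      setNames(rep(stats::rbeta(1, config$cre_freq_beta[1],
                                config$cre_freq_beta[2]),
                   length(freqs)), names(freqs))
    else freqs
    if (!is.null(config$rare_allele_low_prob) &&
        runif(1) < config$rare_allele_low_prob) {
      # orient the effect so the minority allele is the lower-expressed one:
      # a rare alternate allele reduces expression (delta < 0), a common one
      # means the rare reference-like allele is the low one (delta > 0)
      delta <- sign(mean(gene_freqs) - 0.5) * abs(delta)
    }
    carrier <- rbinom(nrow(geno_md), 1,
                      gene_freqs[geno_md$population]) == 1
    names(carrier) <- geno_md$genotype
    u <- rnorm(nrow(geno_md), 0, config$genotype_sd)
    names(u) <- geno_md$genotype
    v <- rnorm(nrow(md), 0, config$replicate_sd)
    depth <- rnbinom(nrow(md), mu = config$depth_mean,
                     size = config$depth_dispersion)
    eta <- config$baseline_logit + delta * carrier[md$genotype] +
      u[md$genotype] + v - config$mapping_bias_logit
    wild <- rbinom(nrow(md), depth, plogis(eta))
    keep <- depth > 0
    counts[[j]] <- tibble::tibble(
      gene = genes[j], sample = md$sample[keep],
      genotype = md$genotype[keep], replicate = md$replicate[keep],
      population = md$population[keep], continent = md$continent[keep],
      latitude = md$latitude[keep],
      wild_count = wild[keep], ref_count = (depth - wild)[keep])
    deltas[j] <- delta
    carriers[[j]] <- tibble::tibble(gene = genes[j],
                                    genotype = geno_md$genotype,
                                    carrier = unname(carrier))
    freq_rows[[j]] <- tibble::tibble(gene = genes[j],
                                     population = names(gene_freqs),
                                     freq_alt = unname(gene_freqs))
  }
  truth <- list(
    genes = tibble::tibble(gene = genes, delta = deltas),
    carriers = dplyr::bind_rows(carriers),
    frequencies = dplyr::bind_rows(freq_rows),
    sigma_g = config$genotype_sd, sigma_r = config$replicate_sd)
  out <- list(counts = dplyr::bind_rows(counts), metadata = md, truth = truth)
  class(out) <- "ase_simulation"
  out
}

#' Simulate a total-expression count matrix coupled to CRE carrier status
#'
#' Per-gene baseline expression is log-normal across genes; expected counts of
#' samples whose genotype carries the higher-expressed CRE allele are
#' multiplied by `total_expression_coupling`, and counts are drawn
#' negative-binomially. The higher-expressed allele is the alternate allele
#' when `delta > 0` and the reference allele otherwise, so the coupling always
#' raises expression of high-allele carriers.
#'
#' @param config a [simulation_config()].
#' @param truth the `truth` component of [simulate_ase_dataset()] output.
#' @param metadata the matching sample metadata.
#' @param seed integer seed.
#' @param base_meanlog,base_sdlog log-normal parameters of per-gene baseline
#'   mean counts.
#' @return integer matrix, genes x samples.
#' @export
simulate_total_expression <- function(config, truth, metadata,
                                      seed = config$seed,
                                      base_meanlog = log(50),
                                      base_sdlog = 1) {
  genes <- truth$genes$gene
  carr <- tidyr::pivot_wider(truth$carriers, names_from = "genotype",
                             values_from = "carrier")
  if (!identical(carr$gene, genes)) carr <- carr[match(genes, carr$gene), ]
  cmat <- as.matrix(carr[, -1])
  if (!all(metadata$genotype %in% colnames(cmat)))
    stop("metadata genotypes do not match simulation truth")
  set.seed(.gene_seed(seed, 0L))
  base <- exp(rnorm(length(genes), base_meanlog, base_sdlog))
  # carrier of the HIGH allele: alternate carriers when delta > 0, else the rest
  high <- cmat[, metadata$genotype, drop = FALSE]
  flip <- truth$genes$delta < 0
  high[flip, ] <- 1 - high[flip, ]
  mu <- base * config$total_expression_coupling^high
  m <- matrix(rnbinom(length(mu), mu = mu, size = config$depth_dispersion),
              nrow = length(genes),
              dimnames = list(genes, metadata$sample))
  m
}

#' Simulate a mixed-mechanism study dataset
#'
#' Combines three gene classes under one sampling design, emulating the
#' composition a genome-wide ASE survey faces: `cline` genes whose alternate
#' CRE allele has latitude-structured frequencies (and whose carrier status
#' is coupled to total expression), `spectrum` genes with CRE variation at
#' per-gene Beta-distributed frequencies but no cline, and `null` genes with
#' no CRE variation at all. Latitudinal differentiation in total expression
#' then arises only through the cline genes' CRE alleles, so ASE should be
#' enriched among latitudinally differentiated genes — the end-to-end signal
#' the clinal analysis is meant to recover.
#'
#' @param seed master seed.
#' @param n_cline,n_spectrum,n_null genes per class.
#' @param cline_freqs alternate-allele frequency by latitude class for the
#'   cline genes.
#' @param freq_beta Beta shape parameters of the spectrum genes' per-gene
#'   allele frequency.
#' @param coupling total-expression coupling of CRE carrier status for the
#'   two CRE-variable classes.
#' @param cre_effect_sd CRE effect SD for the CRE-variable classes.
#' @param ... further arguments passed to every class's
#'   [simulation_config()] (design sizes, depths, noise SDs).
#' @return list: `counts`, `metadata`, `expression` (matrix), `classes`
#'   (gene, class), `truths` (per-class simulation truth).
#' @export
simulate_study_mixture <- function(seed = 1L, n_cline = 60, n_spectrum = 45,
                                   n_null = 45,
                                   cline_freqs = c(temperate = 0.2,
                                                   tropical = 0.8),
                                   freq_beta = c(0.6, 0.6), coupling = 1.5,
                                   cre_effect_sd = 0.8, ...) {
  mk <- function(n_genes, prefix, seed_off, ...) {
    cfg <- simulation_config(n_genes = n_genes, ...)
    s <- simulate_ase_dataset(cfg, seed = as.integer(seed + seed_off))
    e <- simulate_total_expression(cfg, s$truth, s$metadata,
                                   seed = as.integer(seed + seed_off + 1L))
    ren <- function(x) sub("^gene", prefix, x)
    s$counts$gene <- ren(s$counts$gene)
    s$truth$genes$gene <- ren(s$truth$genes$gene)
    s$truth$carriers$gene <- ren(s$truth$carriers$gene)
    s$truth$frequencies$gene <- ren(s$truth$frequencies$gene)
    rownames(e) <- ren(rownames(e))
    list(sim = s, expr = e)
  }
  a <- mk(n_cline, "cline", 0L, cre_effect_sd = cre_effect_sd,
          cre_freq_by_population = cline_freqs,
          total_expression_coupling = coupling, ...)
  b <- mk(n_spectrum, "spec", 50021L, cre_effect_sd = cre_effect_sd,
          cre_freq_beta = freq_beta, rare_allele_low_prob = 0.8,
          total_expression_coupling = coupling, ...)
  c0 <- mk(n_null, "null", 100003L, cre_effect_sd = 0,
           total_expression_coupling = 1, ...)
  counts <- dplyr::bind_rows(a$sim$counts, b$sim$counts, c0$sim$counts)
  expr <- rbind(a$expr, b$expr, c0$expr)
  classes <- tibble::tibble(
    gene = c(a$sim$truth$genes$gene, b$sim$truth$genes$gene,
             c0$sim$truth$genes$gene),
    class = rep(c("cline", "spectrum", "null"),
                c(n_cline, n_spectrum, n_null)))
  list(counts = counts, metadata = a$sim$metadata, expression = expr,
       classes = classes,
       truths = list(cline = a$sim$truth, spectrum = b$sim$truth,
                     null = c0$sim$truth))
}

#' Simulate site pileups for SNP-filter testing
#'
#' True SNP sites are heterozygous and emit the two alleles at ~50:50;
#' non-SNP sites emit sequencing errors binomially at `error_rate`, all toward
#' the same alternate base (the worst-case systematic error the support
#' threshold is designed for).
#'
#' @param n_sites number of sites.
#' @param depth_range integer interval `c(min, max)` for uniform depths.
#' @param true_snp_fraction proportion of sites that are real SNPs.
#' @param error_rate per-base error probability in `[0, 1)`.
#' @param seed integer seed.
#' @param chrom chromosome name for all sites.
#' @return tibble: `chrom`, `pos`, `depth`, `count_A/C/G/T`, and the
#'   ground-truth flag `true_snp`. Reference base is A, alternate base C.
#' @export
simulate_pileups <- function(n_sites, depth_range = c(15, 100),
                             true_snp_fraction = 0.1, error_rate = 0.01,
                             seed = 1L, chrom = "chr1") {
  stopifnot(n_sites >= 1, length(depth_range) == 2)
  if (depth_range[1] > depth_range[2] || depth_range[1] < 1)
    stop("empty depth range")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must lie in [0, 1)")
  set.seed(as.integer(seed))
  depth <- sample(seq(depth_range[1], depth_range[2]), n_sites,
                  replace = TRUE)
  is_snp <- runif(n_sites) < true_snp_fraction
  alt <- integer(n_sites)
  alt[is_snp] <- rbinom(sum(is_snp), depth[is_snp], 0.5)
  alt[!is_snp] <- rbinom(sum(!is_snp), depth[!is_snp], error_rate)
  tibble::tibble(chrom = chrom, pos = seq_len(n_sites), depth = depth,
                 count_A = depth - alt, count_C = alt,
                 count_G = 0L, count_T = 0L, true_snp = is_snp)
}

#' Expand an allele count table into per-read SNP observations
#'
#' Testing utility for the counting stage: each counted read becomes
#' `sites_per_read` per-site allele observations inside its gene's interval,
#' optionally with independent per-site call flips at `flip_rate` (0 gives an
#' error-free chain whose per-gene counts reproduce the input exactly).
#'
#' @param counts allele count table (`gene`, `sample`, `wild_count`,
#'   `ref_count`).
#' @param seed integer seed.
#' @param sites_per_read sites observed per read (1 or 2).
#' @param flip_rate probability a site-level call is flipped.
#' @param gene_length interval length allotted to each gene.
#' @return list: `assignments` (sample, read_id, chrom, pos, allele),
#'   `intervals` (gene, chrom, start, end; 0-based half-open), `sites`
#'   (gene, chrom, pos).
#' @export
simulate_read_assignments <- function(counts, seed = 1L, sites_per_read = 2,
                                      flip_rate = 0, gene_length = 1000L) {
  stopifnot(sites_per_read %in% c(1, 2))
  genes <- sort(unique(counts$gene))
  intervals <- tibble::tibble(
    gene = genes, chrom = "chr1",
    start = (seq_along(genes) - 1L) * gene_length,
    end = seq_along(genes) * gene_length)
  sites <- tibble::tibble(
    gene = rep(genes, each = 2), chrom = "chr1",
    pos = as.vector(vapply(seq_along(genes), function(i)
      intervals$start[i] + c(100L, 200L) + 1L, integer(2))))
  set.seed(as.integer(seed))
  out <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    nw <- counts$wild_count[i]; nr <- counts$ref_count[i]
    n <- nw + nr
    if (n == 0) next
    g <- counts$gene[i]
    sp <- sites$pos[sites$gene == g]
    allele <- rep(c("wild", "reference"), c(nw, nr))
    rid <- sprintf("%s_%s_read%04d", g, counts$sample[i], seq_len(n))
    a1 <- tibble::tibble(sample = counts$sample[i], read_id = rid,
                         chrom = "chr1", pos = sp[1], allele = allele)
    if (sites_per_read == 2) {
      second <- runif(n) < 0.5
      a2 <- a1[second, ]
      a2$pos <- sp[2]
      a1 <- rbind(a1, a2)
    }
    if (flip_rate > 0) {
      fl <- runif(nrow(a1)) < flip_rate
      a1$allele[fl] <- ifelse(a1$allele[fl] == "wild", "reference", "wild")
    }
    out[[i]] <- a1
  }
  list(assignments = dplyr::bind_rows(out), intervals = intervals,
       sites = sites)
}
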