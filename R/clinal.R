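#' Counts-per-million normalization and low-expression filter
#'
#' cpm = count / library size x 1e6, with library sizes taken as column sums
#' unless supplied. Genes are retained when they reach at least `min_cpm` in
#' at least `min_samples` samples (both comparisons non-strict, matching the
#' "at least 1 cpm in at least 10 samples" rule).
#'
#' @param counts integer matrix, genes x samples.
#' @param min_cpm,min_samples filter thresholds (defaults 1 and 10).
#' @param lib_size optional library sizes (must be positive).
#' @return list: `counts` (filtered), `cpm` (filtered), `retained` (gene ids),
#'   `lib_size`.
#' @export
cpm_and_filter <- function(counts, min_cpm = 1, min_samples = 10,
                           lib_size = NULL) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  lib_size <- lib_size %||% colSums(counts)
  if (any(lib_size <= 0)) stop("zero library size")
  cpm <- sweep(counts, 2, lib_size, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  list(counts = counts[keep, , drop = FALSE],
       cpm = cpm[keep, , drop = FALSE],
       retained = rownames(counts)[keep], lib_size = lib_size)
}

#' Down-sample a count matrix to a fixed total per sample
#'
#' Per sample, draws exactly `target_total` reads without replacement across
#' genes proportional to their counts (multivariate hypergeometric, realized
#' by sequential conditional hypergeometric draws), mirroring down-sampling
#' of reads to a fixed coverage level. Column sums equal the target exactly;
#' per-gene proportions are preserved in expectation.
#'
#' @param counts integer matrix, genes x samples.
#' @param target_total reads to keep per sample; must not exceed any library
#'   size.
#' @param seed integer seed.
#' @return down-sampled integer matrix of the same shape.
#' @export
downsample_counts <- function(counts, target_total, seed = 1L) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  ls <- colSums(counts)
  if (any(target_total > ls))
    stop("target_total exceeds library size of sample(s): ",
         paste(head(colnames(counts)[target_total > ls]), collapse = ", "))
  set.seed(as.integer(seed))
  out <- counts
  G <- nrow(counts)
  for (s in seq_len(ncol(counts))) {
    remaining <- ls[s]
    left <- target_total
    for (g in seq_len(G)) {
      cg <- counts[g, s]
      x <- if (left == 0L) 0L
      else if (remaining == cg) left
      else rhyper(1, cg, remaining - cg, left)
      out[g, s] <- x
      left <- left - x
      remaining <- remaining - cg
    }
  }
  storage.mode(out) <- "integer"
  out
}

#' Latitudinal differential-expression test for one continent
#'
#' Default pluggable test: Welch two-sample comparison of log2(cpm + 0.5)
#' between the tropical and temperate samples of the continent. Reports the
#' tropical-minus-temperate mean log2 difference, the p-value, and its BH
#' adjustment. Downstream clinal statistics depend only on the signs and
#' p-values, so any per-gene two-group test can stand in via `test_fun`.
#'
#' @param cpm cpm matrix (genes x samples).
#' @param metadata sample metadata (`sample`, `latitude`, `continent`).
#' @param continent continent to analyse.
#' @param test_fun function(x_tropical, x_temperate) returning a p-value;
#'   default Welch t-test.
#' @return tibble: `gene`, `log2_fold` (tropical - temperate), `p`, `fdr`.
#' @export
latitudinal_de_test <- function(cpm, metadata, continent, test_fun = NULL) {
  md <- metadata[metadata$continent == continent, , drop = FALSE]
  if (!nrow(md)) stop("no samples for continent ", continent)
  md <- md[md$sample %in% colnames(cpm), , drop = FALSE]
  trop <- md$sample[md$latitude == "tropical"]
  temp <- md$sample[md$latitude == "temperate"]
  if (length(trop) < 2 || length(temp) < 2)
    stop("each latitude class needs >= 2 samples on continent ", continent)
  lt <- log2(cpm[, trop, drop = FALSE] + 0.5)
  lc <- log2(cpm[, temp, drop = FALSE] + 0.5)
  test_fun <- test_fun %||% function(x, y) {
    tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
  }
  p <- vapply(seq_len(nrow(cpm)), function(i) test_fun(lt[i, ], lc[i, ]),
              numeric(1))
  tibble::tibble(gene = rownames(cpm),
                 log2_fold = rowMeans(lt) - rowMeans(lc),
                 p = p, fdr = bh_fdr(p))
}

#' Binomial confidence interval (Wilson or Clopper-Pearson)
#'
#' Wilson uses the score inversion without continuity correction
#' ([stats::prop.test()]); Clopper-Pearson uses exact beta quantiles
#' ([stats::binom.test()]). Both always contain x/n.
#'
#' @param x successes, `0 <= x <= n`.
#' @param n trials, `n >= 1`.
#' @param method `"wilson"` or `"clopper_pearson"`.
#' @param level confidence level.
#' @return numeric `c(lower, upper)`.
#' @export
binomial_ci <- function(x, n, method = c("wilson", "clopper_pearson"),
                        level = 0.95) {
  method <- match.arg(method)
  if (n < 1 || x < 0 || x > n || x != round(x) || n != round(n))
    stop("invalid x or n")
  ci <- if (method == "wilson")
    suppressWarnings(prop.test(x, n, conf.level = level,
                               correct = FALSE)$conf.int)
  else binom.test(x, n, conf.level = level)$conf.int
  as.numeric(ci)
}

#' Round a proportion to whole percent, half away from zero
#'
#' Matches the printed style of reported confidence intervals (e.g. 0.7954 ->
#' 80).
#'
#' @param p proportion(s) in `[0, 1]`.
#' @return integer percent(s).
#' @export
percent_round <- function(p) {
  sign(p) * floor(abs(p) * 100 + 0.5)
}

#' Cross-continent sign concordance of latitudinal expression differences
#'
#' Among genes significant on at least one continent (at `fdr_threshold` on
#' the chosen column) and tested on both, counts the four (sign A, sign B)
#' quadrants and the proportion with the same direction of change, with 95%
#' binomial confidence intervals by both Wilson (no continuity correction)
#' and Clopper-Pearson.
#'
#' @param resultsA,resultsB per-gene test tables from
#'   [latitudinal_de_test()] (columns `gene`, `log2_fold`, `p`, `fdr`).
#' @param fdr_threshold significance threshold (default 0.20).
#' @param sig_col column the threshold applies to, `"fdr"` or `"p"`.
#' @param level confidence level.
#' @return list: `quadrants` (table of sign combinations), `n`, `concordant`,
#'   `proportion`, `ci_wilson`, `ci_clopper_pearson`; `proportion` is `NA`
#'   with a `note` when no gene qualifies.
#' @export
sign_concordance <- function(resultsA, resultsB, fdr_threshold = 0.2,
                             sig_col = c("fdr", "p"), level = 0.95) {
  sig_col <- match.arg(sig_col)
  both <- dplyr::inner_join(resultsA, resultsB, by = "gene",
                            suffix = c("_A", "_B"))
  sel <- paste0(sig_col, c("_A", "_B"))
  sig <- (both[[sel[1]]] < fdr_threshold & !is.na(both[[sel[1]]])) |
    (both[[sel[2]]] < fdr_threshold & !is.na(both[[sel[2]]]))
  q <- both[sig & both$log2_fold_A != 0 & both$log2_fold_B != 0, ,
            drop = FALSE]
  if (!nrow(q))
    return(list(quadrants = table(signA = integer(), signB = integer()),
                n = 0L, concordant = 0L, proportion = NA_real_,
                ci_wilson = c(NA, NA), ci_clopper_pearson = c(NA, NA),
                note = "no significant genes"))
  sA <- sign(q$log2_fold_A); sB <- sign(q$log2_fold_B)
  conc <- sum(sA == sB)
  n <- nrow(q)
  list(quadrants = table(signA = sA, signB = sB), n = n, concordant = conc,
       proportion = conc / n,
       ci_wilson = binomial_ci(conc, n, "wilson", level),
       ci_clopper_pearson = binomial_ci(conc, n, "clopper_pearson", level))
}

#' Tie-corrected Spearman rank correlation
#'
#' Wraps [stats::cor.test()]: p-value via the t approximation by default, or
#' the exact permutation null for small tie-free samples.
#'
#' @param x,y numeric vectors, equal length >= 3.
#' @param exact request the exact p-value (only honoured for n <= 8 without
#'   ties, otherwise falls back to the t approximation).
#' @return list `rho`, `p`; both `NA` with a `note` for constant input.
#' @export
spearman_correlation <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, note = "constant vector"))
  use_exact <- exact && length(x) <= 8 && !anyDuplicated(x) &&
    !anyDuplicated(y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = use_exact))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities no larger than the
#' observed table's ([stats::fisher.test()]); the odds ratio is the
#' conditional maximum-likelihood estimate. Degenerate margins give p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list `odds_ratio`, `p`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (sum(table) == 0 || any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(odds_ratio = NA_real_, p = 1))
  ft <- fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Enrichment of ASE among latitudinally differentiated genes
#'
#' Builds the 2x2 table of (latitudinal differentiation x significant ASE)
#' membership over the gene universe and applies the Fisher exact test.
#'
#' @param latitudinal_genes,ase_genes character vectors, subsets of
#'   `universe`.
#' @param universe all tested genes.
#' @return list: `table`, `fisher` (odds ratio + p), `prop_ase_latitudinal`,
#'   `prop_ase_other`, `degenerate` flag when a margin is empty.
#' @export
ase_enrichment <- function(latitudinal_genes, ase_genes, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(latitudinal_genes %in% universe) || !all(ase_genes %in% universe))
    stop("gene sets must be subsets of the universe")
  lat <- universe %in% latitudinal_genes
  ase <- universe %in% ase_genes
  tab <- matrix(c(sum(lat & ase), sum(lat & !ase),
                  sum(!lat & ase), sum(!lat & !ase)), 2, 2, byrow = TRUE,
                dimnames = list(latitudinal = c("yes", "no"),
                                ase = c("yes", "no")))
  list(table = tab, fisher = fisher_exact_2x2(tab),
       prop_ase_latitudinal = if (sum(lat)) mean(ase[lat]) else NA_real_,
       prop_ase_other = if (sum(!lat)) mean(ase[!lat]) else NA_real_,
       degenerate = any(rowSums(tab) == 0) || any(colSums(tab) == 0))
}

#' Population-level ASE means and latitudinal ASE differences for one gene
#'
#' Fits the binomial mixed model with Population as a fixed effect (cell
#' means coding; genotype and replicate random effects retained) and returns
#' the per-population mean ASE on the logit scale plus the tropical-minus-
#' temperate difference per continent. A population absent for the gene
#' leaves its continent's difference `NA`.
#'
#' @param data per-gene allele count rows with `population`, `latitude`,
#'   `continent` columns.
#' @param nagq quadrature nodes.
#' @return list: `population_means` (population, latitude, continent,
#'   mean_ase_logit), `latitudinal_diff` (continent, ase_diff), `fit`.
#' @export
population_ase_means <- function(data, nagq = 9) {
  data$population <- factor(data$population)
  fit <- fit_binomial_glmm(data, ~ 0 + population, nagq = nagq)
  pm <- tibble::tibble(population = levels(data$population),
                       mean_ase_logit = unname(fit$coefficients))
  key <- unique(data[, c("population", "latitude", "continent")])
  key$population <- as.character(key$population)
  pm <- dplyr::left_join(pm, key, by = "population")
  diffs <- dplyr::summarise(
    dplyr::group_by(pm, .data$continent),
    ase_diff = {
      tr <- .data$mean_ase_logit[.data$latitude == "tropical"]
      te <- .data$mean_ase_logit[.data$latitude == "temperate"]
      if (length(tr) == 1 && length(te) == 1) tr - te else NA_real_
    }, .groups = "drop")
  list(population_means = pm, latitudinal_diff = diffs, fit = fit)
}

#' Likelihood-ratio test for a latitude effect on ASE in one gene
#'
#' Compares the binomial mixed model with Latitude + Continent + Latitude x
#' Continent fixed effects against the model without the latitude terms
#' (main effect and interaction dropped jointly; 2 df by default, or the
#' 1-df interaction-only variant).
#'
#' @param data per-gene allele count rows covering all four populations.
#' @param drop `"latitude_and_interaction"` (2 df) or `"interaction"` (1 df).
#' @param nagq quadrature nodes.
#' @return one-row tibble: `lrt`, `df`, `p`, `converged`.
#' @export
ase_latitude_test <- function(data,
                              drop = c("latitude_and_interaction",
                                       "interaction"),
                              nagq = 9) {
  drop <- match.arg(drop)
  pops <- unique(data[, c("latitude", "continent")])
  if (nrow(pops) < 4)
    stop("all latitude x continent combinations must be present")
  data$latitude <- factor(data$latitude)
  data$continent <- factor(data$continent)
  full <- fit_binomial_glmm(data, ~ latitude * continent, nagq = nagq)
  red_form <- if (drop == "latitude_and_interaction") ~continent
  else ~ latitude + continent
  red <- fit_binomial_glmm(data, red_form, nagq = nagq)
  df <- if (drop == "latitude_and_interaction") 2 else 1
  lrt <- max(0, 2 * (full$loglik - red$loglik))
  tibble::tibble(lrt = lrt, df = df,
                 p = pchisq(lrt, df, lower.tail = FALSE),
                 converged = full$converged && red$converged)
}

#' Latitudinal ASE differences for many genes
#'
#' Convenience wrapper running [population_ase_means()] (and optionally
#' [ase_latitude_test()]) per gene.
#'
#' @param table allele count table.
#' @param genes genes to process.
#' @param nagq quadrature nodes.
#' @param latitude_test also run the latitude LRT per gene.
#' @return tibble with one row per (gene, continent): `ase_diff`, plus
#'   `lat_p` when requested.
#' @export
latitudinal_ase_differences <- function(table, genes = NULL, nagq = 9,
                                        latitude_test = FALSE) {
  genes <- genes %||% sort(unique(table$gene))
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    d <- table[table$gene == genes[i], , drop = FALSE]
    res <- tryCatch({
      pam <- population_ase_means(d, nagq = nagq)
      x <- pam$latitudinal_diff
      x$gene <- genes[i]
      if (latitude_test)
        x$lat_p <- tryCatch(ase_latitude_test(d, nagq = nagq)$p,
                            error = function(e) NA_real_)
      x
    }, error = function(e) NULL)
    out[[i]] <- res
  }
  dplyr::bind_rows(out)
}

#' Power-matched ASE enrichment via coverage down-sampling
#'
#' ASE detection power grows with allele-informative coverage, so an
#' enrichment of ASE in one gene set can be a coverage artefact. This
#' re-tests enrichment after hypergeometric thinning of the higher-coverage
#' set's allele counts so that the two sets' per-gene total-count
#' distributions match by quantile, then re-runs the ASE tests and the Fisher
#' enrichment.
#'
#' @param table allele count table covering both gene sets.
#' @param set1,set2 character vectors of gene ids; `set1` plays the role of
#'   the latitudinally differentiated set in the output table.
#' @param seed integer seed for the thinning draws.
#' @param fdr_threshold,min_replicated_genotypes,nagq passed to
#'   [ase_test_table()].
#' @return list: `enrichment` (after matching), `ase` (matched test table),
#'   `thin_factor` (per-gene), `matched_set` which set was thinned.
#' @export
power_matched_enrichment <- function(table, set1, set2, seed = 1L,
                                     fdr_threshold = 0.2,
                                     min_replicated_genotypes = 12,
                                     nagq = 9) {
  genes <- union(set1, set2)
  tb <- table[table$gene %in% genes, , drop = FALSE]
  tot <- dplyr::summarise(
    dplyr::group_by(tb, .data$gene),
    total = sum(.data$wild_count + .data$ref_count), .groups = "drop")
  t1 <- tot$total[tot$gene %in% set1]
  t2 <- tot$total[tot$gene %in% set2]
  if (!length(t1) || !length(t2)) stop("both gene sets need coverage data")
  hi <- if (stats::median(t1) >= stats::median(t2)) "set1" else "set2"
  hi_genes <- if (hi == "set1") set1 else set2
  lo_tot <- if (hi == "set1") t2 else t1
  hi_tot <- tot[tot$gene %in% hi_genes, , drop = FALSE]
  r <- (rank(hi_tot$total) - 0.5) / nrow(hi_tot)
  target <- quantile(lo_tot, probs = r, type = 1)
  fac <- pmin(1, target / hi_tot$total)
  names(fac) <- hi_tot$gene
  set.seed(as.integer(seed))
  thin_row <- function(w, r, f) {
    n <- w + r
    k <- round(f * n)
    if (k >= n) return(c(w, r))
    x <- rhyper(1, w, r, k)
    c(x, k - x)
  }
  for (g in hi_tot$gene) {
    idx <- which(tb$gene == g)
    f <- fac[[g]]
    if (f >= 1) next
    for (i in idx) {
      wr <- thin_row(tb$wild_count[i], tb$ref_count[i], f)
      tb$wild_count[i] <- wr[1]; tb$ref_count[i] <- wr[2]
    }
  }
  ase <- ase_test_table(tb, fdr_threshold = fdr_threshold,
                        min_replicated_genotypes = min_replicated_genotypes,
                        nagq = nagq)
  universe <- ase$gene
  enr <- ase_enrichment(intersect(set1, universe),
                        ase$gene[ase$significant], universe)
  list(enrichment = enr, ase = ase,
       thin_factor = fac, matched_set = hi)
}

#' Total-expression effect of the major versus minor CRE allele
#'
#' For genes with minor-allele frequency below `maf_threshold` and lines
#' carrying both alleles, compares mean cpm of lines carrying the major
#' allele against lines carrying the minor allele: per-gene log2
#' major/minor ratio, the fraction of genes where the major allele is higher
#' expressed, and a one-sample t test of the mean log2 ratio against 0.
#'
#' @param line_calls per-line allele calls (gene, genotype, allele).
#' @param frequencies `per_gene` table from [allele_frequencies()].
#' @param cpm cpm matrix (genes x samples).
#' @param metadata sample metadata mapping samples to genotypes.
#' @param maf_threshold MAF cutoff (default 0.30).
#' @return list: `per_gene` (gene, mean_cpm_major, mean_cpm_minor,
#'   log2_ratio), `fraction_major_higher`, `mean_log2_ratio`, `t`, `p`, `n`.
#' @export
major_minor_expression <- function(line_calls, frequencies, cpm, metadata,
                                   maf_threshold = 0.30) {
  keep <- frequencies$gene[frequencies$maf < maf_threshold &
                             frequencies$maf > 0]
  keep <- intersect(keep, rownames(cpm))
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    g <- keep[i]
    major <- frequencies$major_allele[frequencies$gene == g]
    lc <- line_calls[line_calls$gene == g, , drop = FALSE]
    smaj <- metadata$sample[metadata$genotype %in%
                              lc$genotype[lc$allele == major]]
    smin <- metadata$sample[metadata$genotype %in%
                              lc$genotype[lc$allele != major]]
    smaj <- intersect(smaj, colnames(cpm))
    smin <- intersect(smin, colnames(cpm))
    if (!length(smaj) || !length(smin)) next
    mmaj <- mean(cpm[g, smaj]); mmin <- mean(cpm[g, smin])
    rows[[i]] <- tibble::tibble(gene = g, mean_cpm_major = mmaj,
                                mean_cpm_minor = mmin,
                                log2_ratio = log2(mmaj / mmin))
  }
  per_gene <- dplyr::bind_rows(rows)
  if (!nrow(per_gene))
    return(list(per_gene = per_gene, fraction_major_higher = NA_real_,
                mean_log2_ratio = NA_real_, t = NA_real_, p = NA_real_,
                n = 0L))
  lr <- per_gene$log2_ratio[is.finite(per_gene$log2_ratio)]
  tt <- if (length(lr) >= 2) t.test(lr, mu = 0) else NULL
  list(per_gene = per_gene,
       fraction_major_higher = mean(lr > 0),
       mean_log2_ratio = mean(lr),
       t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       p = if (is.null(tt)) NA_real_ else tt$p.value,
       n = length(lr))
}

#' Per-region enrichment of a gene set (inversions / chromosome arms)
#'
#' For each region, a Fisher exact test of gene-set membership against region
#' membership over the mapped universe, with BH adjustment across regions.
#' Genes without a region mapping are excluded with a warning; a single
#' region makes the test degenerate and is flagged.
#'
#' @param gene_set character vector of genes of interest.
#' @param universe all genes considered.
#' @param gene_to_region data frame `gene`, `region` (one region per gene).
#' @return tibble: `region`, `in_set_in_region`, `odds_ratio`, `p`, `fdr`,
#'   `degenerate`.
#' @export
region_enrichment <- function(gene_set, universe, gene_to_region) {
  stopifnot(all(c("gene", "region") %in% names(gene_to_region)))
  if (anyDuplicated(gene_to_region$gene))
    stop("each gene must map to exactly one region")
  unmapped <- setdiff(universe, gene_to_region$gene)
  if (length(unmapped))
    warning(length(unmapped), " unmapped gene(s) excluded")
  universe <- intersect(universe, gene_to_region$gene)
  gene_set <- intersect(gene_set, universe)
  reg <- gene_to_region$region[match(universe, gene_to_region$gene)]
  regions <- sort(unique(reg))
  degenerate <- length(regions) < 2
  rows <- lapply(regions, function(rg) {
    inr <- reg == rg
    ins <- universe %in% gene_set
    tab <- matrix(c(sum(ins & inr), sum(ins & !inr),
                    sum(!ins & inr), sum(!ins & !inr)), 2, 2, byrow = TRUE)
    fe <- fisher_exact_2x2(tab)
    tibble::tibble(region = rg, in_set_in_region = sum(ins & inr),
                   odds_ratio = fe$odds_ratio, p = fe$p)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_fdr(out$p)
  out$degenerate <- degenerate
  out
}

#' Correlation between ASE magnitude and total-expression difference
#'
#' Per gene: ASE magnitude (difference between the high and low expression
#' groups in mean log2 wild/reference ratio, from the grouping) and the log2
#' ratio of mean cpm of high-allele versus low-allele lines. Returns the
#' Spearman correlation of the two and the fraction of genes where
#' high-allele lines have higher total expression.
#'
#' @param grouping result of [group_alleles()] (uses `summary` and
#'   `line_calls`).
#' @param cpm cpm matrix.
#' @param metadata sample metadata.
#' @param exclude_single_line_groups drop genes where either allele group has
#'   a single line (default TRUE).
#' @return list: `per_gene` (gene, ase_magnitude, log2_cpm_ratio),
#'   `spearman`, `fraction_high_higher`, `n`.
#' @export
ase_total_correlation <- function(grouping, cpm, metadata,
                                  exclude_single_line_groups = TRUE) {
  lc <- grouping$line_calls
  rows <- vector("list", nrow(grouping$summary))
  for (i in seq_len(nrow(grouping$summary))) {
    g <- grouping$summary$gene[i]
    if (!g %in% rownames(cpm)) next
    x <- lc[lc$gene == g, , drop = FALSE]
    nh <- sum(x$allele == "high"); nl <- sum(x$allele == "low")
    if (nh == 0 || nl == 0) next
    if (exclude_single_line_groups && (nh < 2 || nl < 2)) next
    sh <- intersect(metadata$sample[metadata$genotype %in%
                                      x$genotype[x$allele == "high"]],
                    colnames(cpm))
    sl <- intersect(metadata$sample[metadata$genotype %in%
                                      x$genotype[x$allele == "low"]],
                    colnames(cpm))
    if (!length(sh) || !length(sl)) next
    rows[[i]] <- tibble::tibble(
      gene = g, ase_magnitude = grouping$summary$ase_magnitude[i],
      log2_cpm_ratio = log2(mean(cpm[g, sh]) / mean(cpm[g, sl])))
  }
  per_gene <- dplyr::bind_rows(rows)
  sp <- if (nrow(per_gene) >= 3)
    spearman_correlation(per_gene$ase_magnitude, per_gene$log2_cpm_ratio)
  else list(rho = NA_real_, p = NA_real_)
  list(per_gene = per_gene, spearman = sp,
       fraction_high_higher = if (nrow(per_gene))
         mean(per_gene$log2_cpm_ratio > 0) else NA_real_,
       n = nrow(per_gene))
}

#' Flag outlier samples on principal components of expression
#'
#' Principal components of standardized log2 cpm; samples whose PC1 or PC2
#' score exceeds `k_sd` standard deviations of that component's scores are
#' flagged.
#'
#' @param cpm cpm matrix (genes x samples), >= 3 samples.
#' @param k_sd flagging threshold in SD units (default 3; `Inf` flags none).
#' @return tibble: `sample`, `pc1`, `pc2`, `outlier`.
#' @export
qc_outliers <- function(cpm, k_sd = 3) {
  if (ncol(cpm) < 3) stop("need >= 3 samples")
  x <- log2(cpm + 0.5)
  v <- apply(x, 1, sd)
  x <- x[v > 0, , drop = FALSE]
  if (!nrow(x))
    return(tibble::tibble(sample = colnames(cpm), pc1 = 0, pc2 = 0,
                          outlier = FALSE))
  xs <- t(scale(t(x)))
  pc <- prcomp(t(xs), center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  sc <- pc$x[, seq_len(k), drop = FALSE]
  out <- rep(FALSE, ncol(cpm))
  for (j in seq_len(k)) {
    s <- sd(sc[, j])
    if (s > 0) out <- out | abs(sc[, j]) > k_sd * s
  }
  tibble::tibble(sample = colnames(cpm), pc1 = sc[, 1],
                 pc2 = if (k >= 2) sc[, 2] else 0, outlier = out)
}
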