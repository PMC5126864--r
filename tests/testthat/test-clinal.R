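test_that("cpm computation and the expression filter follow the rule", {
  m <- matrix(c(100, 900), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  cf <- cpm_and_filter(m, min_samples = 1)
  expect_equal(cf$cpm[, 1], c(g1 = 1e5, g2 = 9e5))
  expect_equal(colSums(cf$cpm), c(s1 = 1e6))

  # gene at exactly 1 cpm in exactly 10 samples is retained (non-strict)
  n_samp <- 12
  lib <- 1e6
  counts <- matrix(1000, 3, n_samp,
                   dimnames = list(c("edge", "rich", "zero"),
                                   paste0("s", 1:n_samp)))
  counts["edge", ] <- c(rep(1, 10), 0, 0)
  counts["zero", ] <- 0
  counts["rich", ] <- lib - colSums(counts[c("edge", "zero"), , drop = FALSE])
  cf2 <- cpm_and_filter(counts, min_cpm = 1, min_samples = 10)
  expect_true("edge" %in% cf2$retained)
  expect_false("zero" %in% cf2$retained)
  expect_error(cpm_and_filter(matrix(0, 2, 2)), "library")
})

test_that("down-sampling is exact, reproducible and unbiased", {
  set.seed(3)
  m <- matrix(rpois(60, 200), 12, 5,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  m1 <- m[, 1, drop = FALSE]
  expect_identical(downsample_counts(m1, colSums(m1), seed = 1)[, 1],
                   m1[, 1])  # target = library size -> identity
  d1 <- downsample_counts(m, 500, seed = 9)
  expect_true(all(colSums(d1) == 500))
  expect_identical(d1, downsample_counts(m, 500, seed = 9))
  expect_error(downsample_counts(m, max(colSums(m)) + 1))
  # unbiasedness: mean over seeds within 3 SE of input proportions
  p_in <- m[, 1] / sum(m[, 1])
  draws <- sapply(1:60, function(s) downsample_counts(m, 500, seed = s)[, 1])
  p_hat <- rowMeans(draws) / 500
  se <- sqrt(p_in * (1 - p_in) / (500 * 60))
  expect_true(all(abs(p_hat - p_in) < 3 * se + 1e-9))
})

make_expr_md <- function(n_per = 6) {
  tibble::tibble(
    sample = paste0("s", seq_len(4 * n_per)),
    genotype = paste0("g", seq_len(4 * n_per)),
    replicate = "r1",
    population = rep(c("C1_temperate", "C1_tropical", "C2_temperate",
                       "C2_tropical"), each = n_per),
    latitude = rep(rep(c("temperate", "tropical"), each = n_per), 2),
    continent = rep(c("C1", "C2"), each = 2 * n_per))
}

test_that("the latitudinal DE test recovers planted fold changes", {
  md <- make_expr_md(8)
  set.seed(5)
  n_genes <- 200
  lam <- matrix(500, n_genes, nrow(md),
                dimnames = list(sprintf("g%03d", 1:n_genes), md$sample))
  shifted <- 1:20
  trop1 <- md$continent == "C1" & md$latitude == "tropical"
  lam[shifted, trop1] <- 1000
  counts <- matrix(rpois(length(lam), lam), nrow(lam),
                   dimnames = dimnames(lam))
  cpm <- cpm_and_filter(counts, min_samples = 1)$cpm
  de <- latitudinal_de_test(cpm, md, "C1")
  # cpm normalization shrinks the planted 2-fold by the library-size ratio
  expected <- 1 - log2(sum(lam[, which(trop1)[1]]) / (n_genes * 500))
  expect_equal(mean(de$log2_fold[shifted]), expected, tolerance = 0.1)
  expect_error(latitudinal_de_test(cpm, md[md$latitude == "tropical", ],
                                   "C1"), ">= 2 samples")
})

test_that("the latitudinal DE test is calibrated under the null", {
  md <- make_expr_md(8)
  set.seed(6)
  lam <- matrix(500, 400, nrow(md),
                dimnames = list(sprintf("n%03d", 1:400), md$sample))
  counts <- matrix(rpois(length(lam), lam), nrow(lam),
                   dimnames = dimnames(lam))
  cpm <- cpm_and_filter(counts, min_samples = 1)$cpm
  de <- latitudinal_de_test(cpm, md, "C2")
  ks <- suppressWarnings(ks.test(de$p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(de$log2_fold)), 0.02)
})

test_that("binomial confidence intervals match their closed-form oracles", {
  for (xn in list(c(53, 59), c(159, 192), c(3, 10), c(0, 10), c(10, 10))) {
    w <- binomial_ci(xn[1], xn[2], "wilson")
    cp <- binomial_ci(xn[1], xn[2], "clopper_pearson")
    expect_equal(w, oracle_wilson(xn[1], xn[2]), tolerance = 1e-7)
    expect_equal(cp, oracle_clopper(xn[1], xn[2]), tolerance = 1e-7)
    ph <- xn[1] / xn[2]
    expect_true(w[1] <= ph && ph <= w[2])
    expect_true(cp[1] <= ph && ph <= cp[2])
  }
  expect_identical(binomial_ci(0, 10, "clopper_pearson")[1], 0)
  expect_error(binomial_ci(5, 4))
  expect_equal(percent_round(c(0.7954, 0.9526, 0.765)), c(80, 95, 77))
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(12)
  for (p in c(0.1, 0.5, 0.9)) {
    x <- rbinom(4000, 50, p)
    cov <- mean(vapply(x, function(xi) {
      ci <- oracle_clopper(xi, 50)
      ci[1] <= p && p <= ci[2]
    }, logical(1)))
    expect_gte(cov, 0.95 - 3 * sqrt(0.05 * 0.95 / 4000))
  }
})

test_that("sign concordance counts quadrants and is symmetric", {
  A <- tibble::tibble(gene = c("a", "b", "c"), log2_fold = c(1, 2, -1),
                      p = 0.001, fdr = 0.01)
  B <- tibble::tibble(gene = c("a", "b", "c"), log2_fold = c(0.5, -2, -3),
                      p = 0.5, fdr = 0.9)
  sc <- sign_concordance(A, B, fdr_threshold = 0.2)
  expect_equal(sc$n, 3)
  expect_equal(sc$concordant, 2)
  expect_equal(sc$proportion, 2 / 3)
  sc_swap <- sign_concordance(B, A, fdr_threshold = 0.2)
  expect_equal(sc_swap$proportion, sc$proportion)
  none <- sign_concordance(dplyr::mutate(A, fdr = 1),
                           dplyr::mutate(B, fdr = 1))
  expect_true(is.na(none$proportion))
  expect_match(none$note, "no significant")
})

test_that("Spearman correlation matches exhaustive permutation enumeration", {
  expect_equal(spearman_correlation(1:10, 1:10)$rho, 1)
  expect_equal(spearman_correlation(1:10, 10:1)$rho, -1)
  x <- c(2.3, 1.1, 5.4, 3.3, 4.0)
  y <- c(0.7, 0.2, 2.2, 3.0, 1.4)
  got <- spearman_correlation(x, y, exact = TRUE)
  ora <- oracle_spearman(x, y)
  expect_equal(got$rho, ora$rho, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-12)
  const <- spearman_correlation(rep(1, 5), 1:5)
  expect_true(is.na(const$rho))
  expect_match(const$note, "constant")
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  t1 <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  f1 <- fisher_exact_2x2(t1)
  expect_equal(f1$p, 0.4857, tolerance = 1e-4)
  expect_equal(f1$p, oracle_fisher(t1), tolerance = 1e-10)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
  t3 <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(t3)$p, oracle_fisher(t3), tolerance = 1e-10)
  # random small tables vs enumeration
  set.seed(9)
  for (i in 1:20) {
    tt <- matrix(rpois(4, 3), 2)
    if (any(rowSums(tt) == 0) || any(colSums(tt) == 0)) next
    expect_equal(fisher_exact_2x2(tt)$p, oracle_fisher(tt),
                 tolerance = 1e-10)
  }
  expect_equal(fisher_exact_2x2(matrix(0L, 2, 2))$p, 1)
})

test_that("ASE enrichment builds the membership table correctly", {
  uni <- paste0("g", 1:100)
  lat <- paste0("g", 1:20)
  ase <- paste0("g", c(1:10, 51:60))
  e <- ase_enrichment(lat, ase, uni)
  expect_equal(unname(e$table[1, ]), c(10, 10))
  expect_equal(unname(e$table[2, ]), c(10, 70))
  expect_equal(e$prop_ase_latitudinal, 0.5)
  expect_equal(e$prop_ase_other, 0.125)
  expect_true(ase_enrichment(lat, uni, uni)$degenerate)
  expect_error(ase_enrichment(c(lat, "zz"), ase, uni), "subsets")
  expect_error(ase_enrichment(lat, ase, character(0)), "empty")
})

test_that("region enrichment flags extremes and degenerate maps", {
  map <- tibble::tibble(gene = paste0("g", 1:60),
                        region = rep(c("2L", "2R", "3R"), each = 20))
  res <- region_enrichment(paste0("g", 1:10), paste0("g", 1:60), map)
  expect_equal(res$region[which.min(res$p)], "2L")
  expect_true(all(res$fdr >= res$p))
  one <- region_enrichment(paste0("g", 1:5), paste0("g", 1:20),
                           map[1:20, ])
  expect_true(all(one$degenerate))
  expect_warning(region_enrichment("g1", c("g1", "zz"), map), "unmapped")
})

test_that("major/minor expression effect is a direct cpm comparison", {
  lc <- tibble::tibble(gene = "g1", genotype = paste0("g", 1:10),
                       allele = rep(c("high", "low"), c(2, 8)))
  fr <- tibble::tibble(gene = "g1", n_lines = 10, freq_high = 0.2,
                       major_allele = "low", maf = 0.2)
  md <- tibble::tibble(sample = paste0("s", 1:10),
                       genotype = paste0("g", 1:10))
  cpm <- matrix(rep(c(10, 20), c(2, 8)), 1, 10,
                dimnames = list("g1", paste0("s", 1:10)))
  mm <- major_minor_expression(lc, fr, cpm, md)
  expect_equal(mm$per_gene$log2_ratio, 1)  # major 20 vs minor 10
  expect_equal(mm$fraction_major_higher, 1)
  # MAF at or above threshold excluded
  fr2 <- fr; fr2$maf <- 0.3
  mm2 <- major_minor_expression(lc, fr2, cpm, md)
  expect_equal(mm2$n, 0)
})

test_that("expression coupling favoring the major allele is recovered", {
  cfg <- simulation_config(n_genes = 25, cre_effect_fixed = 1.2,
                           cre_freq_by_population = 0.75,
                           genotype_sd = 0.05, replicate_sd = 0.05,
                           depth_mean = 200, depth_dispersion = 50,
                           total_expression_coupling = 2)
  sim <- simulate_ase_dataset(cfg, seed = 71)
  expr <- simulate_total_expression(cfg, sim$truth, sim$metadata, seed = 72)
  cpm <- cpm_and_filter(expr, min_samples = 10)$cpm
  gr <- group_alleles(sim$counts)
  fr <- allele_frequencies(gr$line_calls, sim$metadata)
  mm <- major_minor_expression(gr$line_calls, fr$per_gene, cpm,
                               sim$metadata, maf_threshold = 0.40)
  # high allele (delta > 0 alternate, frequency 0.75) is the major allele and
  # carries the 2x coupling
  expect_gte(mm$n, 10)
  expect_gt(mm$fraction_major_higher, 0.5)
  expect_gt(mm$mean_log2_ratio, 0)
})

test_that("frequency-oriented effects make the minor allele the low one", {
  cfg <- simulation_config(n_genes = 300, cre_effect_sd = 0.8,
                           cre_freq_beta = c(0.6, 0.6),
                           rare_allele_low_prob = 1)
  sim <- simulate_ase_dataset(cfg, seed = 81)
  f <- tapply(sim$truth$carriers$carrier, sim$truth$carriers$gene, mean)
  d <- sim$truth$genes$delta[match(names(f), sim$truth$genes$gene)]
  skewed <- abs(f - 0.5) > 0.1
  expect_true(all(sign(d[skewed]) == sign(f[skewed] - 0.5)))
})

test_that("ASE magnitude vs total expression uses the group means", {
  groupings <- list(
    summary = tibble::tibble(gene = c("g1", "g2"),
                             ase_magnitude = c(2, 0.5)),
    line_calls = tibble::tibble(
      gene = rep(c("g1", "g2"), each = 4),
      genotype = rep(paste0("g", 1:4), 2),
      group = "x",
      allele = rep(c("high", "high", "low", "low"), 2)))
  md <- tibble::tibble(sample = paste0("s", 1:4),
                       genotype = paste0("g", 1:4))
  cpm <- rbind(g1 = c(40, 40, 10, 10), g2 = c(5, 5, 10, 10))
  colnames(cpm) <- md$sample
  at <- ase_total_correlation(groupings, cpm, md)
  expect_equal(sort(at$per_gene$log2_cpm_ratio), c(-1, 2))
  expect_equal(at$fraction_high_higher, 0.5)
})

test_that("ASE enrichment is recovered when cline genes carry CRE effects", {
  base <- list(n_genes = 20, genotypes_per_population = 6,
               replicated_genotypes_per_population = 4,
               total_expression_coupling = 1)
  cline <- do.call(simulation_config, c(base, list(
    cre_effect_sd = 1,
    cre_freq_by_population = c(temperate = 0.2, tropical = 0.8))))
  null <- do.call(simulation_config, c(base, list(cre_effect_sd = 0)))
  sA <- simulate_ase_dataset(cline, seed = 51)
  sB <- simulate_ase_dataset(null, seed = 52)
  sB$counts$gene <- sub("gene", "null", sB$counts$gene)
  counts <- dplyr::bind_rows(sA$counts, sB$counts)
  ase <- ase_test_table(counts, min_replicated_genotypes = 8)
  lat_genes <- unique(sA$counts$gene)
  enr <- ase_enrichment(intersect(lat_genes, ase$gene),
                        ase$gene[ase$significant], ase$gene)
  expect_gt(enr$fisher$odds_ratio, 1)
  expect_gt(enr$prop_ase_latitudinal, enr$prop_ase_other)
})

test_that("power matching removes coverage-driven enrichment", {
  sim_set <- function(depth, prefix, seed) {
    cfg <- simulation_config(n_genes = 25, genotypes_per_population = 6,
                             replicated_genotypes_per_population = 4,
                             cre_effect_sd = 0.45, depth_mean = depth)
    s <- simulate_ase_dataset(cfg, seed = seed)
    s$counts$gene <- sub("gene", prefix, s$counts$gene)
    s$counts
  }
  hi <- sim_set(400, "hi", 61)
  lo <- sim_set(25, "lo", 62)
  counts <- dplyr::bind_rows(hi, lo)
  set1 <- unique(hi$gene); set2 <- unique(lo$gene)
  before <- ase_test_table(counts, min_replicated_genotypes = 8)
  enr_before <- ase_enrichment(set1, before$gene[before$significant],
                               before$gene)
  pm <- power_matched_enrichment(counts, set1, set2, seed = 5,
                                 min_replicated_genotypes = 8)
  expect_equal(pm$matched_set, "set1")
  expect_true(all(pm$thin_factor <= 1))
  # same effect-size distribution in both sets: once coverage is matched the
  # apparent enrichment collapses toward parity
  p_lat_b <- enr_before$prop_ase_latitudinal
  p_oth_b <- enr_before$prop_ase_other
  expect_gt(p_lat_b - p_oth_b, 0.2)  # the planted coverage confound
  p_lat_a <- pm$enrichment$prop_ase_latitudinal
  p_oth_a <- pm$enrichment$prop_ase_other
  expect_lt(abs(p_lat_a - p_oth_a), p_lat_b - p_oth_b)
  # reproducible
  pm2 <- power_matched_enrichment(counts, set1, set2, seed = 5,
                                  min_replicated_genotypes = 8)
  expect_identical(pm$enrichment$table, pm2$enrichment$table)
})

test_that("PCA outlier flagging finds a planted outlier", {
  set.seed(8)
  base <- matrix(rnbinom(3000, mu = 100, size = 10), 100, 30,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:30)))
  cpm <- cpm_and_filter(base, min_samples = 1)$cpm
  expect_false(any(qc_outliers(cpm, k_sd = Inf)$outlier))
  cpm_out <- cpm
  cpm_out[, 1] <- sample(cpm[, 1] * c(rep(30, 50), rep(1 / 30, 50)))
  qc <- qc_outliers(cpm_out, k_sd = 3)
  expect_true(qc$outlier[qc$sample == "s1"])
  ident <- matrix(50, 20, 5, dimnames = list(paste0("g", 1:20),
                                             paste0("s", 1:5)))
  expect_false(any(qc_outliers(ident)$outlier))
  expect_error(qc_outliers(ident[, 1:2]), ">= 3")
})

test_that("population ASE means contrast latitudes within continents", {
  cfg <- simulation_config(n_genes = 1, cre_effect_sd = 0, genotype_sd = 0.05,
                           replicate_sd = 0.1, depth_mean = 300)
  sim <- simulate_ase_dataset(cfg, seed = 17)
  pam <- population_ase_means(sim$counts)
  expect_equal(nrow(pam$population_means), 4)
  expect_true(all(abs(pam$latitudinal_diff$ase_diff) < 0.25))  # symmetric null
  # missing continent errors in the latitude test
  half <- sim$counts[sim$counts$continent == "C1", ]
  expect_error(ase_latitude_test(half), "combinations")
})
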