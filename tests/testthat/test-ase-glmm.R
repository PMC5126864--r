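test_that("Gauss-Hermite rule integrates Gaussian moments exactly", {
  gh <- gauss_hermite(9)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-10)
  expect_equal(sum(gh$weights * gh$nodes^4), 0.75 * sqrt(pi),
               tolerance = 1e-10)
})

test_that("with variance components constrained to zero the fit is a plain GLM", {
  for (s in 1:5) {
    d <- make_gene_data(n_geno = 10, depth = 30, prob = 0.4, seed = s)
    f <- fit_binomial_glmm(d, re_genotype = FALSE, re_replicate = FALSE)
    g <- glm(cbind(wild_count, ref_count) ~ 1, binomial, d)
    expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
    expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
  }
  # with a covariate
  d <- make_gene_data(n_geno = 12, depth = 50, seed = 9)
  d$group <- factor(rep(c("a", "b"), length.out = nrow(d)))
  f <- fit_binomial_glmm(d, ~group, re_genotype = FALSE,
                         re_replicate = FALSE)
  g <- glm(cbind(wild_count, ref_count) ~ group, binomial, d)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-5)
})

test_that("symmetric data give a null fit", {
  d <- tibble::tibble(genotype = rep(paste0("g", 1:15), each = 2),
                      replicate = rep(c("r1", "r2"), 15),
                      wild_count = 50, ref_count = 50)
  f <- fit_binomial_glmm(d)
  expect_equal(unname(coef(f)), 0, tolerance = 1e-3)
  expect_lt(f$sigma_g, 0.02)
  expect_lt(f$sigma_r, 0.02)
})

test_that("singleton genotypes make the genotype effect observation-level", {
  d <- make_gene_data(n_geno = 14, depth = 60, seed = 4, replicated = 0)
  fg <- fit_binomial_glmm(d, re_genotype = TRUE, re_replicate = FALSE)
  fr <- fit_binomial_glmm(d, re_genotype = FALSE, re_replicate = TRUE)
  expect_equal(fg$loglik, fr$loglik, tolerance = 1e-5)
  expect_equal(fg$sigma_g, fr$sigma_r, tolerance = 1e-3)
})

test_that("log-likelihood is stable when quadrature nodes are doubled", {
  d <- sim_glmm_gene(n_geno = 12, depth = 150, sigma_g = 1, sigma_r = 0.3,
                     seed = 6)
  f <- fit_binomial_glmm(d)
  expect_lt(abs(glmm_loglik(f, 18, 18) - f$loglik), 1e-4)
})

test_that("fit agrees with the lme4 cross-check", {
  skip_if_not_installed("lme4")
  d <- sim_glmm_gene(n_geno = 16, depth = 100, beta0 = 0.3, sigma_g = 0.8,
                     sigma_r = 0.2, seed = 11)
  f <- fit_binomial_glmm(d)
  d$obs <- seq_len(nrow(d))
  m <- lme4::glmer(cbind(wild_count, ref_count) ~ 1 + (1 | genotype) +
                     (1 | obs), data = d, family = binomial)
  expect_equal(unname(coef(f)), unname(lme4::fixef(m)), tolerance = 0.02)
  expect_equal(f$sigma_g, sqrt(lme4::VarCorr(m)$genotype[1]),
               tolerance = 0.05)
  expect_equal(f$loglik, as.numeric(logLik(m)), tolerance = 0.3)
})

test_that("likelihood is invariant to relabeling and allele swap", {
  d <- sim_glmm_gene(n_geno = 10, depth = 80, beta0 = 0.5, sigma_g = 0.6,
                     sigma_r = 0.2, seed = 13)
  f <- fit_binomial_glmm(d)
  d2 <- d
  d2$genotype <- paste0("zz_", rev(d$genotype))
  f2 <- fit_binomial_glmm(d2)
  expect_equal(f2$loglik, f$loglik, tolerance = 1e-5)
  d3 <- d
  d3$wild_count <- d$ref_count
  d3$ref_count <- d$wild_count
  f3 <- fit_binomial_glmm(d3)
  expect_equal(f3$loglik, f$loglik, tolerance = 1e-5)
  expect_equal(unname(coef(f3)), -unname(coef(f)), tolerance = 1e-3)
  expect_equal(f3$sigma_g, f$sigma_g, tolerance = 1e-3)
})

test_that("the ASE LRT is non-negative with a valid boundary p-value", {
  for (s in 1:25) {
    d <- sim_glmm_gene(n_geno = 8, depth = 30,
                       sigma_g = runif(1, 0, 1.2),
                       sigma_r = runif(1, 0, 0.5), seed = 100 + s)
    r <- test_ase(d)
    expect_gte(r$lrt, 0)
    expect_true(is.na(r$p) || (r$p > 0 && r$p <= 1))
  }
  # exchangeable data: statistic ~0, p ~1
  d <- tibble::tibble(genotype = rep(paste0("g", 1:12), each = 2),
                      replicate = rep(c("r1", "r2"), 12),
                      wild_count = 40, ref_count = 40)
  r <- test_ase(d)
  expect_lt(r$lrt, 1e-3)
  expect_gt(r$p, 0.9)
  # mixture reference halves the chi-square tail
  d2 <- sim_glmm_gene(n_geno = 10, depth = 60, sigma_g = 0.8, seed = 3)
  r1 <- test_ase(d2, null_dist = "chisq1")
  r2 <- test_ase(d2, null_dist = "mixture")
  expect_equal(r2$p, r1$p / 2, tolerance = 1e-8)
})

test_that("strong genotype signal is detected with high power", {
  hits <- 0
  for (s in 1:25) {
    d <- sim_glmm_gene(n_geno = 12, depth = 200, sigma_g = 1.5,
                       sigma_r = 0.2, seed = 200 + s)
    hits <- hits + (test_ase(d)$p < 0.05)
  }
  expect_gte(hits / 25, 0.9)
})

test_that("degenerate inputs are rejected loudly", {
  d <- make_gene_data(n_geno = 4, seed = 1)
  d0 <- d; d0$wild_count <- 0; d0$ref_count <- 0
  expect_error(fit_binomial_glmm(d0), "zero total")
  d1 <- d[d$genotype == "g1", ]
  expect_error(fit_binomial_glmm(d1), "2 genotypes")
  dna <- d; dna$wild_count[1] <- -1
  expect_error(fit_binomial_glmm(dna), "non-negative")
})

test_that("BH adjustment matches the hand-computed step-up rule", {
  expect_equal(bh_fdr(c(0.05, 0.1)), c(0.1, 0.1))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(77)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    expect_equal(order(adj[order(p)]), seq_along(p))  # order-preserving
  }
  expect_error(bh_fdr(c(0.5, 1.2)))
})

test_that("gene inclusion requires replicated genotypes with data", {
  md_rows <- function(gene, geno, reps) {
    tibble::tibble(gene = gene, genotype = geno,
                   replicate = paste0("r", seq_len(reps)),
                   wild_count = 5, ref_count = 5)
  }
  full <- dplyr::bind_rows(lapply(1:12, function(i)
    md_rows("gA", paste0("g", i), 2)))
  expect_equal(gene_inclusion_filter(full), "gA")
  eleven <- full[full$genotype != "g12" | full$replicate != "r2", ]
  expect_equal(gene_inclusion_filter(eleven), character(0))
  expect_equal(gene_inclusion_filter(eleven, min_replicated_genotypes = 0),
               "gA")
})
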