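# Independent brute-force oracles, kept free of the package code paths they
# check.

# smallest m >= 1 with P(X >= m) < alpha, X ~ Bin(depth, e), by explicit
# probability-mass summation
oracle_min_support <- function(depth, e = 0.01, alpha = 1e-4) {
  pmf <- dbinom(0:depth, depth, e)
  for (m in 1:(depth + 1)) {
    tail <- if (m > depth) 0 else sum(pmf[(m + 1):(depth + 1)])
    if (tail < alpha) return(m)
  }
  depth + 1L
}

# Benjamini-Hochberg step-up by direct definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

# exhaustive-permutation Spearman: rho by rank correlation, two-sided p as
# the null fraction with |rho| at least as extreme
oracle_spearman <- function(x, y) {
  rho_of <- function(a, b) cor(rank(a), rank(b))
  obs <- rho_of(x, y)
  perms <- perm_all(length(y))
  rhos <- apply(perms, 1, function(idx) rho_of(x, y[idx]))
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}

perm_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perm_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- dhyper(xs, c1, n - c1, r1)
  obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Wilson score interval, closed form (no continuity correction)
oracle_wilson <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  ph <- x / n
  c0 <- (ph + z^2 / (2 * n)) / (1 + z^2 / n)
  hw <- z / (1 + z^2 / n) * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2))
  c(c0 - hw, c0 + hw)
}

# Clopper-Pearson via beta quantiles
oracle_clopper <- function(x, n, level = 0.95) {
  a <- 1 - level
  lo <- if (x == 0) 0 else qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  c(lo, hi)
}

# small balanced one-population design for GLMM tests
make_gene_data <- function(n_geno = 8, depth = 40, prob = 0.5, seed = 1,
                           replicated = n_geno) {
  set.seed(seed)
  reps <- rep(c(2, 1), c(replicated, n_geno - replicated))
  g <- rep(seq_len(n_geno), reps)
  r <- unlist(lapply(reps, seq_len))
  n <- rep(depth, length(g))
  w <- rbinom(length(g), n, prob)
  tibble::tibble(genotype = paste0("g", g), replicate = paste0("r", r),
                 wild_count = w, ref_count = n - w)
}

# simulate from the analysis model directly (for null / power studies)
sim_glmm_gene <- function(n_geno = 16, n_rep = 2, depth = 100, beta0 = 0,
                          sigma_g = 0, sigma_r = 0.2, seed = 1) {
  set.seed(seed)
  g <- rep(seq_len(n_geno), each = n_rep)
  u <- rnorm(n_geno, 0, sigma_g)[g]
  v <- rnorm(length(g), 0, sigma_r)
  n <- rep(depth, length(g))
  w <- rbinom(length(g), n, plogis(beta0 + u + v))
  tibble::tibble(genotype = paste0("g", g),
                 replicate = paste0("r", rep(seq_len(n_rep), n_geno)),
                 wild_count = w, ref_count = n - w)
}
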