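#' Gauss-Hermite nodes and weights
#'
#' Nodes and weights for the physicists' Gauss-Hermite rule (weight
#' \eqn{e^{-x^2}}), computed by the Golub-Welsch eigenvalue method. Used to
#' build the adaptive quadrature grids of [fit_binomial_glmm()].
#'
#' @param n number of nodes (>= 1).
#' @return list with numeric vectors `nodes` and `weights`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1, n == round(n))
  n <- as.integer(n)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

.glmm_prepare <- function(data, fixed, re_genotype) {
  stopifnot(is.data.frame(data))
  need <- c("wild_count", "ref_count", "genotype")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  wild <- as.numeric(data$wild_count)
  ref <- as.numeric(data$ref_count)
  if (any(wild < 0) || any(ref < 0)) stop("allele counts must be non-negative")
  tot <- wild + ref
  if (all(tot == 0)) stop("all rows have zero total count")
  keep <- tot > 0
  data <- data[keep, , drop = FALSE]
  wild <- wild[keep]; tot <- tot[keep]
  gid <- as.integer(factor(data$genotype))
  if (re_genotype && length(unique(gid)) < 2)
    stop("genotype random effect requires >= 2 genotypes")
  X <- model.matrix(fixed, data)
  if (qr(X)$rank < ncol(X)) {
    e <- simpleError("rank-deficient fixed-effect design")
    class(e) <- c("clinase_rank_deficient", class(e))
    stop(e)
  }
  ord <- order(gid)
  list(data = data[ord, , drop = FALSE], wild = wild[ord], total = tot[ord],
       X = X[ord, , drop = FALSE], gid = gid[ord])
}

#' Fit the binomial logit mixed model for one gene
#'
#' Maximum-likelihood fit of
#' \deqn{wild_i \sim Binomial(total_i, logit^{-1}(x_i'\beta + u_{g(i)} + v_i))}
#' with a genotype random effect \eqn{u_g \sim N(0, \sigma_g^2)} and an
#' observation-level (biological replicate) random effect
#' \eqn{v_i \sim N(0, \sigma_r^2)}. The marginal likelihood is integrated by
#' nested adaptive Gauss-Hermite quadrature, exploiting the genotype ->
#' replicate nesting so cost is linear in genotypes, and maximized by bounded
#' quasi-Newton (`optim(method = "L-BFGS-B")`) over the fixed effects and the
#' log standard deviations. The fit is deterministic given data and settings.
#'
#' Either random effect can be omitted, which constrains its variance to
#' exactly zero; with both omitted the fit is an ordinary binomial regression.
#'
#' @param data data frame with columns `wild_count`, `ref_count`, `genotype`,
#'   plus any covariates named in `fixed`. Rows with zero total are dropped.
#' @param fixed one-sided formula for the fixed effects (default `~ 1`).
#' @param re_genotype,re_replicate include the genotype / observation-level
#'   random effect.
#' @param nagq,nagq_inner quadrature nodes for the outer (genotype) and inner
#'   (replicate) integrals; default 9 each.
#' @param start optional list with elements `beta`, `sigma_g`, `sigma_r` used
#'   as additional starting values; the best optimum is kept.
#' @param control passed to [stats::optim()]; defaults
#'   `list(factr = 1e7, maxit = 300)` give ~1e-9 relative tolerance on the
#'   objective.
#' @return object of class `ase_glmm`: `coefficients`, `sigma_g`, `sigma_r`,
#'   `loglik`, `converged`, `nagq`, `n_obs`, `n_genotypes`, `fixed`.
#' @seealso [glmm_loglik()] to re-evaluate the fitted likelihood at other node
#'   counts (accuracy check), [test_ase()] for the ASE likelihood-ratio test.
#' @export
fit_binomial_glmm <- function(data, fixed = ~1, re_genotype = TRUE,
                              re_replicate = TRUE, nagq = 9,
                              nagq_inner = nagq, start = NULL,
                              control = list()) {
  pr <- .glmm_prepare(data, fixed, re_genotype)
  wild <- pr$wild; total <- pr$total; X <- pr$X; gid <- pr$gid
  gstart <- c(0L, cumsum(tabulate(gid)))  # rows already ordered by genotype
  lch <- lchoose(total, wild)
  gh_o <- gauss_hermite(nagq)
  gh_i <- gauss_hermite(nagq_inner)
  lw_o <- log(gh_o$weights); lw_i <- log(gh_i$weights)
  p <- ncol(X)

  g0 <- suppressWarnings(glm.fit(X, wild / total, weights = total,
                                 family = binomial()))
  beta0 <- g0$coefficients
  beta0[!is.finite(beta0)] <- 0
  r <- qlogis((wild + 0.5) / (total + 1)) - drop(X %*% beta0)
  sg0 <- if (re_genotype) {
    s <- sd(tapply(r, gid, mean))
    min(max(ifelse(is.finite(s), s, 0.3), 0.05), 1.5)
  } else 0
  sr0 <- if (re_replicate) 0.3 else 0

  n_re <- re_genotype + re_replicate
  lb <- c(rep(-Inf, p), rep(log(1e-4), n_re))
  ub <- c(rep(Inf, p), rep(log(20), n_re))
  ctrl <- modifyList(list(factr = 1e7, maxit = 300), control)

  cache <- new.env(parent = emptyenv())
  evalpar <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    beta <- par[seq_len(p)]
    sg <- if (re_genotype) exp(par[p + 1]) else 0
    sr <- if (re_replicate) exp(par[p + n_re]) else 0
    res <- glmm_nagq_eval(beta, sg, sr, re_genotype, re_replicate,
                          wild, total, lch, X, gstart,
                          gh_o$nodes, lw_o, gh_i$nodes, lw_i, TRUE)
    cache$par <- par; cache$res <- res
    res
  }
  fn <- function(par) -evalpar(par)$loglik
  gr <- function(par) {
    res <- evalpar(par)
    g <- -res$gbeta
    if (re_genotype) g <- c(g, -res$glog_sigma_g)
    if (re_replicate) g <- c(g, -res$glog_sigma_r)
    g
  }

  starts <- list(c(beta0,
                   if (re_genotype) log(sg0),
                   if (re_replicate) log(sr0)))
  if (!is.null(start)) {
    sb <- if (!is.null(start$beta) && length(start$beta) == p) start$beta else beta0
    starts <- c(starts, list(c(
      sb,
      if (re_genotype) log(max(start$sigma_g %||% sg0, 1e-3)),
      if (re_replicate) log(max(start$sigma_r %||% sr0, 1e-3)))))
  }
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      optim(s, fn, gr, method = "L-BFGS-B", lower = lb, upper = ub,
            control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    e <- simpleError("binomial GLMM optimization failed")
    class(e) <- c("clinase_fit_error", class(e))
    stop(e)
  }
  par <- best$par
  beta <- setNames(par[seq_len(p)], colnames(X))
  out <- list(
    coefficients = beta,
    sigma_g = if (re_genotype) unname(exp(par[p + 1])) else 0,
    sigma_r = if (re_replicate) unname(exp(par[p + n_re])) else 0,
    loglik = -best$value,
    converged = best$convergence == 0,
    message = best$message,
    nagq = c(outer = as.integer(nagq), inner = as.integer(nagq_inner)),
    n_obs = length(wild),
    n_genotypes = length(unique(gid)),
    fixed = fixed,
    re = c(genotype = re_genotype, replicate = re_replicate),
    fit_data = list(wild = wild, total = total, lch = lch, X = X,
                    gstart = gstart)
  )
  class(out) <- "ase_glmm"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-evaluate a fitted GLMM log-likelihood at a chosen quadrature order
#'
#' Used to verify the accuracy contract that the log-likelihood is stable when
#' the number of quadrature nodes is doubled.
#'
#' @param fit an `ase_glmm` object.
#' @param nagq,nagq_inner node counts to evaluate at.
#' @return the marginal log-likelihood at the fitted parameters.
#' @export
glmm_loglik <- function(fit, nagq = fit$nagq[["outer"]],
                        nagq_inner = fit$nagq[["inner"]]) {
  stopifnot(inherits(fit, "ase_glmm"))
  fd <- fit$fit_data
  gh_o <- gauss_hermite(nagq); gh_i <- gauss_hermite(nagq_inner)
  glmm_nagq_eval(unname(fit$coefficients), fit$sigma_g, fit$sigma_r,
                 fit$re[["genotype"]], fit$re[["replicate"]],
                 fd$wild, fd$total, fd$lch, fd$X, fd$gstart,
                 gh_o$nodes, log(gh_o$weights), gh_i$nodes,
                 log(gh_i$weights), FALSE)$loglik
}

#' @export
print.ase_glmm <- function(x, ...) {
  cat("Binomial logit mixed model (nested adaptive GH quadrature)\n")
  cat(sprintf("  %d rows, %d genotypes; nAGQ %d (outer) x %d (inner)\n",
              x$n_obs, x$n_genotypes, x$nagq[["outer"]], x$nagq[["inner"]]))
  cat("  fixed effects:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  sigma_g = %.4f, sigma_r = %.4f\n", x$sigma_g, x$sigma_r))
  cat(sprintf("  loglik = %.4f (%s)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
logLik.ase_glmm <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients) + sum(object$re),
            class = "logLik")
}

#' @export
coef.ase_glmm <- function(object, ...) object$coefficients

#' Likelihood-ratio test for allele-specific expression in one gene
#'
#' Fits the intercept-only binomial logit mixed model with genotype and
#' observation-level random effects, and the reduced model without the
#' genotype effect, and tests the genotype variance component by likelihood
#' ratio. Significant genotype-level heterogeneity in the wild/reference read
#' ratio is the signature of cis-regulatory (allele-specific) variation.
#'
#' @param data per-gene allele count data (see [fit_binomial_glmm()]).
#' @param nagq quadrature nodes per dimension.
#' @param null_dist reference distribution for the statistic: `"chisq1"`
#'   (chi-square, 1 df; conservative because the null value lies on the
#'   boundary) or `"mixture"` (equal mixture of a point mass at 0 and
#'   chi-square 1).
#' @return one-row [tibble::tibble()] with `loglik_full`, `loglik_reduced`,
#'   `lrt`, `p`, `sigma_g`, `sigma_r`, `mean_ref_prop` (inverse-logit of minus
#'   the full-model intercept) and `converged`.
#' @export
test_ase <- function(data, nagq = 9, null_dist = c("chisq1", "mixture")) {
  null_dist <- match.arg(null_dist)
  red <- fit_binomial_glmm(data, ~1, re_genotype = FALSE, re_replicate = TRUE,
                           nagq = nagq)
  full <- fit_binomial_glmm(data, ~1, re_genotype = TRUE, re_replicate = TRUE,
                            nagq = nagq,
                            start = list(beta = unname(red$coefficients),
                                         sigma_g = 0.05,
                                         sigma_r = red$sigma_r))
  conv <- red$converged && full$converged
  lrt <- 2 * (full$loglik - red$loglik)
  if (lrt < 0 && lrt > -1e-6) lrt <- 0
  lrt <- max(lrt, 0)
  p <- if (!conv) NA_real_
  else if (lrt <= 0) 1
  else if (null_dist == "chisq1") pchisq(lrt, df = 1, lower.tail = FALSE)
  else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  tibble::tibble(
    loglik_full = full$loglik, loglik_reduced = red$loglik,
    lrt = lrt, p = p,
    sigma_g = full$sigma_g, sigma_r = full$sigma_r,
    mean_ref_prop = plogis(-unname(full$coefficients[1])),
    converged = conv)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment via [stats::p.adjust()], with input validation.
#'
#' @param pvalues numeric vector in `[0, 1]` (NAs propagate).
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Gene inclusion filter for the ASE test
#'
#' A gene is retained when at least `min_replicated_genotypes` genotypes have
#' allele counts in two biological replicates for that gene, so the
#' observation-level variance is estimable.
#'
#' @param table allele count table with `gene`, `genotype`, `replicate`.
#' @param min_replicated_genotypes threshold (default 12).
#' @return character vector of retained gene ids.
#' @export
gene_inclusion_filter <- function(table, min_replicated_genotypes = 12) {
  stopifnot(all(c("gene", "genotype", "replicate") %in% names(table)))
  reps <- dplyr::summarise(
    dplyr::group_by(table, .data$gene, .data$genotype),
    n_rep = dplyr::n_distinct(.data$replicate), .groups = "drop")
  keep <- dplyr::summarise(
    dplyr::group_by(reps, .data$gene),
    n_replicated = sum(.data$n_rep >= 2), .groups = "drop")
  sort(keep$gene[keep$n_replicated >= min_replicated_genotypes])
}

#' Genome-wide ASE testing with FDR control
#'
#' Applies [gene_inclusion_filter()], runs [test_ase()] per gene, and adjusts
#' p-values by Benjamini-Hochberg. Genes are flagged significant at
#' `fdr < fdr_threshold` (default 0.20, the study-wide level).
#'
#' @param table allele count table (long format, one row per gene x sample).
#' @param fdr_threshold FDR significance level.
#' @param min_replicated_genotypes passed to [gene_inclusion_filter()].
#' @param nagq,null_dist passed to [test_ase()].
#' @return tibble with one row per tested gene: test columns of [test_ase()]
#'   plus `fdr` and `significant`.
#' @export
ase_test_table <- function(table, fdr_threshold = 0.2,
                           min_replicated_genotypes = 12, nagq = 9,
                           null_dist = "chisq1") {
  genes <- gene_inclusion_filter(table, min_replicated_genotypes)
  if (!length(genes)) {
    return(tibble::tibble(gene = character(), loglik_full = numeric(),
                          loglik_reduced = numeric(), lrt = numeric(),
                          p = numeric(), sigma_g = numeric(),
                          sigma_r = numeric(), mean_ref_prop = numeric(),
                          converged = logical(), fdr = numeric(),
                          significant = logical()))
  }
  res <- lapply(genes, function(g) {
    d <- table[table$gene == g, , drop = FALSE]
    dplyr::bind_cols(tibble::tibble(gene = g),
                     test_ase(d, nagq = nagq, null_dist = null_dist))
  })
  res <- dplyr::bind_rows(res)
  res$fdr <- bh_fdr(res$p)
  res$significant <- !is.na(res$fdr) & res$fdr < fdr_threshold
  res
}
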