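#' Per-line log2 wild/reference expression ratios
#'
#' Read counts from biological replicates of a line are summed before the
#' ratio is taken. When either summed count is zero, a pseudocount of 0.5 is
#' added to both alleles (display/ordering only; model fitting always uses
#' raw counts). Lines whose total is zero after summing are excluded with a
#' message.
#'
#' @param data per-gene allele count rows (`genotype`, `wild_count`,
#'   `ref_count`).
#' @return tibble: `genotype`, `wild`, `ref`, `log2_ratio`, sorted by
#'   decreasing ratio.
#' @export
line_log_ratios <- function(data) {
  s <- dplyr::summarise(dplyr::group_by(data, .data$genotype),
                        wild = sum(.data$wild_count),
                        ref = sum(.data$ref_count), .groups = "drop")
  drop <- s$wild + s$ref == 0
  if (any(drop)) {
    message("excluding ", sum(drop), " line(s) with zero total count")
    s <- s[!drop, , drop = FALSE]
  }
  pc <- ifelse(s$wild == 0 | s$ref == 0, 0.5, 0)
  s$log2_ratio <- log2((s$wild + pc) / (s$ref + pc))
  s[order(-s$log2_ratio, s$genotype), ]
}

#' Maximum-likelihood split of lines into high and low expression alleles
#'
#' Lines are sorted by their replicate-summed log2 wild/reference ratio and
#' every ordered split into a top and bottom group (sizes 1 to L-1) is scored
#' by fitting the binomial mixed model with a two-level Group fixed effect
#' (genotype and replicate random effects retained). The split with the
#' maximum log-likelihood wins; ties are broken toward the more balanced
#' split. When all splits are equivalent (exchangeable data) the result is
#' flagged degenerate.
#'
#' @param data per-gene allele count rows (`genotype`, `wild_count`,
#'   `ref_count`, `replicate`).
#' @param nagq quadrature nodes for the underlying model fits.
#' @param max_top_size cap on the top-group size enumerated; the default
#'   (`NULL`) enumerates all L-1 ordered splits. Supplying the number of
#'   non-replicated lines minus one reproduces a narrower enumeration.
#' @return object of class `ase_grouping`: `ratios` (per-line tibble with
#'   `group` labels "top"/"bottom"), `split_size`, `loglik`, `logliks` (per
#'   candidate size), `group_means` (named mean log2 ratios), `ase_magnitude`
#'   (top mean minus bottom mean), `degenerate` flag.
#' @seealso [assign_reference_group()] to complete the result with the
#'   reference-CRE group and per-line allele calls.
#' @export
best_split <- function(data, nagq = 9, max_top_size = NULL) {
  ratios <- line_log_ratios(data)
  L <- nrow(ratios)
  if (L < 2) stop("grouping requires at least 2 lines with data")
  kmax <- min(L - 1L, max_top_size %||% (L - 1L))
  data <- data[data$genotype %in% ratios$genotype, , drop = FALSE]
  lls <- rep(NA_real_, kmax)
  for (k in seq_len(kmax)) {
    top <- ratios$genotype[seq_len(k)]
    d <- data
    d$group <- factor(ifelse(d$genotype %in% top, "top", "bottom"),
                      levels = c("bottom", "top"))
    fit <- fit_binomial_glmm(d, ~group, nagq = nagq)
    lls[k] <- fit$loglik
  }
  tol <- 1e-4
  best_ll <- max(lls)
  cand <- which(lls >= best_ll - tol)
  # tie-break toward the most balanced split, then the smaller top group
  cand <- cand[order(abs(2 * cand - L), cand)]
  k <- cand[1]
  degenerate <- (max(lls) - min(lls)) < tol
  ratios$group <- rep(c("top", "bottom"), c(k, L - k))
  gm <- c(top = mean(ratios$log2_ratio[ratios$group == "top"]),
          bottom = mean(ratios$log2_ratio[ratios$group == "bottom"]))
  out <- list(ratios = ratios, split_size = k, loglik = lls[k],
              logliks = lls, group_means = gm,
              ase_magnitude = unname(gm["top"] - gm["bottom"]),
              degenerate = degenerate)
  class(out) <- "ase_grouping"
  out
}

#' Assign the reference-CRE group and per-line allele calls
#'
#' The group whose mean log2 wild/reference ratio is closest to 0 (wild and
#' reference alleles similarly expressed) is taken to carry the reference CRE
#' allele; the other group carries the alternate allele. If the alternate
#' group's mean ratio is positive the wild allele is the high-expression
#' allele, otherwise the low one. Lines in the alternate group are called
#' carriers of that wild-allele direction, lines in the reference group the
#' opposite. An exact tie in |mean| makes the larger group the reference and
#' sets the degeneracy flag.
#'
#' @param result an `ase_grouping` from [best_split()].
#' @return the completed `ase_grouping`, gaining `reference_group` ("top" or
#'   "bottom"), `wild_allele` ("high"/"low"), `line_calls` (genotype, group,
#'   allele in high/low) and possibly an updated `degenerate` flag.
#' @export
assign_reference_group <- function(result) {
  stopifnot(inherits(result, "ase_grouping"))
  gm <- result$group_means
  a <- abs(gm)
  if (isTRUE(all.equal(a[["top"]], a[["bottom"]]))) {
    sizes <- table(result$ratios$group)
    ref <- names(which.max(sizes[c("top", "bottom")]))
    result$degenerate <- TRUE
  } else {
    ref <- names(which.min(a))
  }
  alt <- setdiff(c("top", "bottom"), ref)
  wild_allele <- if (gm[[alt]] > 0) "high" else "low"
  calls <- result$ratios[, c("genotype", "group")]
  calls$allele <- ifelse(calls$group == alt, wild_allele,
                         setdiff(c("high", "low"), wild_allele))
  result$reference_group <- ref
  result$wild_allele <- wild_allele
  result$line_calls <- calls
  result
}

#' @export
print.ase_grouping <- function(x, ...) {
  cat(sprintf("ML allele grouping: %d lines, top group of %d (loglik %.3f%s)\n",
              nrow(x$ratios), x$split_size, x$loglik,
              if (x$degenerate) ", DEGENERATE" else ""))
  cat(sprintf("  group means (log2 wild/ref): top %.3f, bottom %.3f; ASE magnitude %.3f\n",
              x$group_means[["top"]], x$group_means[["bottom"]],
              x$ase_magnitude))
  if (!is.null(x$reference_group))
    cat(sprintf("  reference-CRE group: %s; wild allele: %s expression\n",
                x$reference_group, x$wild_allele))
  invisible(x)
}

#' Group alleles for many genes
#'
#' Runs [best_split()] + [assign_reference_group()] per gene and returns tidy
#' tables.
#'
#' @param table allele count table.
#' @param genes genes to process (default: all in `table`).
#' @param nagq,max_top_size passed to [best_split()].
#' @return list: `summary` (gene, split_size, loglik, mean_top, mean_bottom,
#'   ase_magnitude, reference_group, wild_allele, degenerate) and
#'   `line_calls` (gene, genotype, group, allele).
#' @export
group_alleles <- function(table, genes = NULL, nagq = 9,
                          max_top_size = NULL) {
  genes <- genes %||% sort(unique(table$gene))
  summ <- vector("list", length(genes))
  calls <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    d <- table[table$gene == genes[i], , drop = FALSE]
    g <- assign_reference_group(best_split(d, nagq = nagq,
                                           max_top_size = max_top_size))
    summ[[i]] <- tibble::tibble(
      gene = genes[i], split_size = g$split_size, loglik = g$loglik,
      mean_top = g$group_means[["top"]],
      mean_bottom = g$group_means[["bottom"]],
      ase_magnitude = g$ase_magnitude,
      reference_group = g$reference_group, wild_allele = g$wild_allele,
      degenerate = g$degenerate)
    calls[[i]] <- dplyr::bind_cols(tibble::tibble(gene = genes[i]),
                                   g$line_calls)
  }
  list(summary = dplyr::bind_rows(summ), line_calls = dplyr::bind_rows(calls))
}

#' High-allele frequencies, major/minor designation and MAF
#'
#' From per-line allele calls, computes the frequency of the high-expression
#' allele per population and pooled over all populations, designates the
#' major allele (pooled frequency >= 0.5, ties to "high"), and the minor
#' allele frequency.
#'
#' @param line_calls tibble `gene`, `genotype`, `allele` (from
#'   [group_alleles()]).
#' @param metadata sample metadata mapping `genotype` to `population`.
#' @return list: `per_population` (gene, population, n_lines, freq_high) and
#'   `per_gene` (gene, n_lines, freq_high, major_allele, maf).
#' @export
allele_frequencies <- function(line_calls, metadata) {
  geno_pop <- unique(metadata[, c("genotype", "population")])
  x <- dplyr::left_join(line_calls, geno_pop, by = "genotype")
  per_pop <- dplyr::summarise(
    dplyr::group_by(x, .data$gene, .data$population),
    n_lines = dplyr::n(),
    freq_high = mean(.data$allele == "high"), .groups = "drop")
  per_gene <- dplyr::summarise(
    dplyr::group_by(x, .data$gene),
    n_lines = dplyr::n(),
    freq_high = mean(.data$allele == "high"), .groups = "drop")
  per_gene$major_allele <- ifelse(per_gene$freq_high >= 0.5, "high", "low")
  per_gene$maf <- pmin(per_gene$freq_high, 1 - per_gene$freq_high)
  list(per_population = per_pop, per_gene = per_gene)
}
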