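#' Minimum supporting reads for a SNP call at a given depth
#'
#' Smallest m >= 1 such that P(X >= m) < alpha for X ~ Binomial(depth,
#' error_rate): the number of supporting reads required so that the
#' probability of that many same-base sequencing errors (the worst case in
#' which every error produces the same incorrect nucleotide at phred 20)
#' stays below `alpha`. Non-decreasing in depth; depth 0 returns 1 (support
#' is impossible, any threshold is vacuously safe).
#'
#' @param depth total read depth (vectorized).
#' @param error_rate per-base error probability, in (0, 1).
#' @param alpha tail probability bound, in (0, 1).
#' @return integer vector of thresholds.
#' @export
min_supporting_reads <- function(depth, error_rate = 0.01, alpha = 1e-4) {
  stopifnot(all(depth >= 0), all(depth == round(depth)))
  if (error_rate <= 0 || error_rate >= 1) stop("error_rate must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  vapply(as.integer(depth), function(d) {
    m <- as.integer(qbinom(alpha, d, error_rate, lower.tail = FALSE)) + 1L
    while (m > 1L &&
           pbinom(m - 2L, d, error_rate, lower.tail = FALSE) < alpha)
      m <- m - 1L
    while (pbinom(m - 1L, d, error_rate, lower.tail = FALSE) >= alpha)
      m <- m + 1L
    m
  }, integer(1))
}

.pileup_base_counts <- function(pileups) {
  bases <- c("count_A", "count_C", "count_G", "count_T")
  miss <- setdiff(bases, names(pileups))
  if (length(miss)) stop("pileups lack columns: ", paste(miss, collapse = ", "))
  as.matrix(pileups[, bases])
}

.intervals_to_granges <- function(intervals, one_based = FALSE) {
  # BED convention: 0-based half-open -> 1-based inclusive
  start <- if (one_based) intervals$start else intervals$start + 1L
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = start, end = intervals$end),
    gene = intervals$gene)
}

.gene_at_positions <- function(chrom, pos, intervals, one_based = FALSE) {
  gr <- .intervals_to_granges(intervals, one_based)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  # absent chromosomes are reported by the caller; silence the seqlevel notice
  hit <- suppressWarnings(GenomicRanges::findOverlaps(q, gr,
                                                      select = "first"))
  ifelse(is.na(hit), NA_character_,
         S4Vectors::mcols(gr)$gene[hit])
}

#' Call and filter SNPs from pileups
#'
#' Applies, in order: minimum total depth; exactly two allele states;
#' minor-state support at least [min_supporting_reads()] of the site's depth;
#' intersection with at least one gene interval; presence in the biallelic
#' whitelist (matching position and allele pair). Removal counts per filter
#' are returned for logging. Chromosomes present in the pileups but absent
#' from the intervals are reported with a warning, not fatal. An empty
#' whitelist yields an empty SNP set.
#'
#' @param pileups tibble with `chrom`, `pos` (1-based) and `count_A/C/G/T`.
#' @param intervals gene intervals (`gene`, `chrom`, `start`, `end`), 0-based
#'   half-open as read from BED by [read_gene_intervals()].
#' @param whitelist biallelic SNP whitelist (`chrom`, `pos`, `ref`, `alt`).
#' @param min_depth minimum total reads at the site (default 15).
#' @param error_rate,alpha parameters of the support threshold.
#' @return list with `snps` (chrom, pos, allele_major, allele_minor, gene) and
#'   `removed`, a named vector of per-filter removal counts.
#' @export
call_and_filter_snps <- function(pileups, intervals, whitelist,
                                 min_depth = 15, error_rate = 0.01,
                                 alpha = 1e-4) {
  cm <- .pileup_base_counts(pileups)
  depth <- rowSums(cm)
  removed <- c(depth = 0L, states = 0L, support = 0L, not_in_gene = 0L,
               whitelist = 0L)

  unknown <- setdiff(unique(pileups$chrom), unique(intervals$chrom))
  if (length(unknown))
    warning("pileup chromosomes absent from intervals: ",
            paste(unknown, collapse = ", "))

  keep <- depth >= min_depth
  removed["depth"] <- sum(!keep)
  pileups <- pileups[keep, , drop = FALSE]; cm <- cm[keep, , drop = FALSE]
  depth <- depth[keep]

  n_states <- rowSums(cm > 0)
  keep <- n_states == 2
  removed["states"] <- sum(!keep)
  pileups <- pileups[keep, , drop = FALSE]; cm <- cm[keep, , drop = FALSE]
  depth <- depth[keep]

  if (nrow(pileups)) {
    srt <- t(apply(cm, 1, sort, decreasing = TRUE))
    minor <- srt[, 2]
    thr <- min_supporting_reads(depth, error_rate, alpha)
    keep <- minor >= thr
  } else keep <- logical(0)
  removed["support"] <- sum(!keep)
  pileups <- pileups[keep, , drop = FALSE]; cm <- cm[keep, , drop = FALSE]

  bases <- c("A", "C", "G", "T")
  if (nrow(pileups)) {
    amaj <- bases[apply(cm, 1, which.max)]
    amin <- vapply(seq_len(nrow(cm)), function(i) {
      o <- order(cm[i, ], decreasing = TRUE)
      bases[o[2]]
    }, character(1))
    gene <- .gene_at_positions(pileups$chrom, pileups$pos, intervals)
    keep <- !is.na(gene)
  } else {
    amaj <- amin <- character(0); gene <- character(0); keep <- logical(0)
  }
  removed["not_in_gene"] <- sum(!keep)
  snps <- tibble::tibble(chrom = pileups$chrom, pos = pileups$pos,
                         allele_major = amaj, allele_minor = amin,
                         gene = gene)[keep, , drop = FALSE]

  if (nrow(snps) && nrow(whitelist)) {
    key <- paste(snps$chrom, snps$pos)
    wkey <- paste(whitelist$chrom, whitelist$pos)
    idx <- match(key, wkey)
    ok <- !is.na(idx)
    same <- ok
    same[ok] <- mapply(function(i, a, b) {
      setequal(c(whitelist$ref[i], whitelist$alt[i]), c(a, b))
    }, idx[ok], snps$allele_major[ok], snps$allele_minor[ok])
    keep <- same
  } else keep <- rep(FALSE, nrow(snps))
  removed["whitelist"] <- sum(!keep)
  list(snps = snps[keep, , drop = FALSE], removed = removed)
}

#' Resolve reads with conflicting allele assignments
#'
#' A read assigned the wild allele at one SNP and the reference allele at
#' another is internally inconsistent. Under the default rule the read is
#' dropped (smallest information loss); under `"drop_snp"` SNPs whose
#' observations come from conflicted reads at a rate above
#' `snp_conflict_threshold` are removed first, and reads still conflicted
#' afterwards are dropped. The output has one allele call per retained read,
#' so no read can contribute to both alleles of a gene.
#'
#' @param assignments tibble: `sample`, `read_id`, `chrom`, `pos`, `allele`
#'   (`"wild"` or `"reference"`); one row per (read, site).
#' @param rule `"drop_read"` (default) or `"drop_snp"`.
#' @param snp_conflict_threshold conflict-rate threshold for `"drop_snp"`.
#' @return list with `calls` (sample, read_id, chrom, pos, allele; one row per
#'   read, `pos` is the read's first observed site) and `removed_snps`
#'   (chrom, pos).
#' @export
resolve_conflicting_reads <- function(assignments,
                                      rule = c("drop_read", "drop_snp"),
                                      snp_conflict_threshold = 0.1) {
  rule <- match.arg(rule)
  empty <- list(calls = tibble::tibble(sample = character(),
                                       read_id = character(),
                                       chrom = character(), pos = integer(),
                                       allele = character()),
                removed_snps = tibble::tibble(chrom = character(),
                                              pos = integer()))
  if (!nrow(assignments)) return(empty)
  stopifnot(all(assignments$allele %in% c("wild", "reference")))
  key <- paste(assignments$sample, assignments$read_id, assignments$chrom,
               assignments$pos)
  if (anyDuplicated(key)) stop("duplicate (read, site) assignment")

  removed_snps <- empty$removed_snps
  rkey <- paste(assignments$sample, assignments$read_id)
  conflicted <- function(a, rk) {
    tab <- dplyr::summarise(
      dplyr::group_by(a, rk = rk),
      n_alleles = dplyr::n_distinct(.data$allele), .groups = "drop")
    tab$rk[tab$n_alleles > 1]
  }
  bad <- conflicted(assignments, rkey)
  if (rule == "drop_snp" && length(bad)) {
    is_bad <- rkey %in% bad
    site <- paste(assignments$chrom, assignments$pos)
    rate <- tapply(is_bad, site, mean)
    drop_sites <- names(rate)[rate > snp_conflict_threshold]
    if (length(drop_sites)) {
      sel <- site %in% drop_sites
      removed_snps <- unique(tibble::tibble(
        chrom = assignments$chrom[sel], pos = assignments$pos[sel]))
      assignments <- assignments[!sel, , drop = FALSE]
      rkey <- paste(assignments$sample, assignments$read_id)
    }
    bad <- conflicted(assignments, rkey)
  }
  keep <- !(rkey %in% bad)
  a <- assignments[keep, , drop = FALSE]
  if (!nrow(a)) return(list(calls = empty$calls, removed_snps = removed_snps))
  calls <- dplyr::summarise(
    dplyr::group_by(a, .data$sample, .data$read_id),
    chrom = .data$chrom[1], pos = .data$pos[which.min(.data$pos)],
    allele = .data$allele[1], .groups = "drop")
  list(calls = calls, removed_snps = removed_snps)
}

#' Count wild and reference alleles per gene and sample
#'
#' Maps each resolved read call to the gene whose interval contains its site
#' and tallies wild and reference reads per (gene, sample). Genes with zero
#' retained reads in a sample yield no row (sparse convention), and the row
#' totals equal the number of retained allele-informative reads.
#'
#' @param calls per-read allele calls from [resolve_conflicting_reads()].
#' @param intervals gene intervals (0-based half-open).
#' @param metadata sample metadata with at least `sample`, `genotype`,
#'   `replicate`, `population`, `latitude`, `continent`.
#' @return allele count table: `gene`, `sample`, metadata columns,
#'   `wild_count`, `ref_count`.
#' @export
count_alleles_per_gene <- function(calls, intervals, metadata) {
  if (!all(calls$sample %in% metadata$sample))
    stop("sample(s) absent from metadata: ",
         paste(head(setdiff(calls$sample, metadata$sample)), collapse = ", "))
  gene <- .gene_at_positions(calls$chrom, calls$pos, intervals)
  calls <- calls[!is.na(gene), , drop = FALSE]
  gene <- gene[!is.na(gene)]
  tab <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(gene = gene, sample = calls$sample,
                                   allele = calls$allele),
                    .data$gene, .data$sample),
    wild_count = sum(.data$allele == "wild"),
    ref_count = sum(.data$allele == "reference"), .groups = "drop")
  dplyr::left_join(tab, metadata, by = "sample")[
    , c("gene", "sample", "genotype", "replicate", "population", "continent",
        "latitude", "wild_count", "ref_count")]
}

#' Reference-allele proportion summaries and bias strata
#'
#' Per-sample and per-gene (pooled) reference-allele proportions, the overall
#' mean per-sample proportion, and per-gene bias strata: pooled reference
#' proportion above `hi` = "toward_reference", below `lo` = "away", else
#' "neutral". Used to check for residual mapping bias and to stratify
#' robustness analyses.
#'
#' @param table allele count table.
#' @param lo,hi stratum boundaries (defaults 0.45 / 0.55).
#' @return list: `per_sample` (sample, ref_prop), `per_gene` (gene, ref_prop,
#'   stratum), `overall_mean_ref_prop`, `n_samples_above_half`.
#' @export
reference_bias_summary <- function(table, lo = 0.45, hi = 0.55) {
  if (!nrow(table)) stop("empty allele count table")
  per_sample <- dplyr::summarise(
    dplyr::group_by(table, .data$sample),
    ref_prop = sum(.data$ref_count) /
      sum(.data$ref_count + .data$wild_count), .groups = "drop")
  per_gene <- dplyr::summarise(
    dplyr::group_by(table, .data$gene),
    ref_prop = sum(.data$ref_count) /
      sum(.data$ref_count + .data$wild_count), .groups = "drop")
  per_gene$stratum <- ifelse(per_gene$ref_prop > hi, "toward_reference",
                             ifelse(per_gene$ref_prop < lo, "away", "neutral"))
  list(per_sample = per_sample, per_gene = per_gene,
       overall_mean_ref_prop = mean(per_sample$ref_prop),
       n_samples_above_half = sum(per_sample$ref_prop > 0.5))
}
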