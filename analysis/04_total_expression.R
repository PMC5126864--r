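#!/usr/bin/env Rscript
# Stage 4: total expression and latitudinal differential expression.
#
# cpm-normalizes the count matrix, applies the >=1 cpm in >=10 samples
# filter, flags PCA outliers, tests tropical vs temperate differential
# expression separately per continent, and measures cross-continent sign
# concordance among significant genes with Wilson and Clopper-Pearson
# binomial intervals. Also quantifies the phenotypic effect of CRE alleles:
# high- vs low-allele and major- vs minor-allele total expression.

suppressMessages(library(clinase))

outdir <- "results"
metadata <- read_sample_metadata(file.path(outdir, "metadata.tsv"))
expr_tbl <- readr::read_tsv(file.path(outdir, "total_expression_counts.tsv"),
                            show_col_types = FALSE)
expr <- as.matrix(expr_tbl[, -1])
rownames(expr) <- expr_tbl$gene

filt <- cpm_and_filter(expr, min_cpm = 1, min_samples = 10)
message(sprintf("%d of %d genes pass the cpm filter", nrow(filt$cpm),
                nrow(expr)))

qc <- qc_outliers(filt$cpm, k_sd = 3)
message(sprintf("%d PCA outlier sample(s) flagged", sum(qc$outlier)))

de <- lapply(c("C1", "C2"), function(cc)
  latitudinal_de_test(filt$cpm, metadata, cc))
names(de) <- c("C1", "C2")
for (cc in names(de))
  readr::write_tsv(de[[cc]], file.path(outdir,
                                       paste0("latitudinal_de_", cc, ".tsv")))

conc <- sign_concordance(de$C1, de$C2, fdr_threshold = 0.2)
if (!is.na(conc$proportion)) {
  message(sprintf(
    "direction concordant for %d of %d significant genes (%.0f%%; Wilson %d-%d%%, Clopper-Pearson %d-%d%%)",
    conc$concordant, conc$n, 100 * conc$proportion,
    percent_round(conc$ci_wilson[1]), percent_round(conc$ci_wilson[2]),
    percent_round(conc$ci_clopper_pearson[1]),
    percent_round(conc$ci_clopper_pearson[2])))
} else {
  message("no significant DE genes; concordance undefined")
}

grouping <- list(
  summary = readr::read_tsv(file.path(outdir, "grouping_summary.tsv"),
                            show_col_types = FALSE),
  line_calls = readr::read_tsv(file.path(outdir, "line_calls.tsv"),
                               show_col_types = FALSE))
freqs <- readr::read_tsv(file.path(outdir, "allele_freq_genes.tsv"),
                         show_col_types = FALSE)

at <- ase_total_correlation(grouping, filt$cpm, metadata)
message(sprintf(
  "high-allele lines more highly expressed for %.0f%% of %d genes (Spearman rho %.2f)",
  100 * at$fraction_high_higher, at$n, at$spearman$rho))
readr::write_tsv(at$per_gene, file.path(outdir, "ase_vs_total.tsv"))

mm <- major_minor_expression(grouping$line_calls, freqs, filt$cpm, metadata,
                             maf_threshold = 0.30)
message(sprintf(
  "major allele higher expressed for %.0f%% of %d MAF<30%% genes (mean log2 ratio %.3f, t-test p %.2g)",
  100 * mm$fraction_major_higher, mm$n, mm$mean_log2_ratio, mm$p))
readr::write_tsv(mm$per_gene, file.path(outdir, "major_minor.tsv"))
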