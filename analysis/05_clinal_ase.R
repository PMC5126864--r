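#!/usr/bin/env Rscript
# Stage 5: latitudinal structure of cis-regulatory variation.
#
# For ASE-significant genes, extracts per-population mean ASE (Population
# fixed effect in the mixed model) and the tropical-minus-temperate ASE
# difference per continent; correlates those differences across continents
# (Spearman); tests enrichment of ASE among genes with parallel latitudinal
# differentiation in total expression (Fisher), with a reference-bias
# stratified robustness check.

suppressMessages(library(clinase))

outdir <- "results"
counts <- read_allele_counts(file.path(outdir, "allele_counts.tsv"))
ase <- readr::read_tsv(file.path(outdir, "ase_tests.tsv"),
                       show_col_types = FALSE)
bias <- readr::read_tsv(file.path(outdir, "reference_bias_genes.tsv"),
                        show_col_types = FALSE)
sig <- ase$gene[ase$significant]

lat_ase <- latitudinal_ase_differences(counts, genes = sig,
                                       latitude_test = TRUE)
readr::write_tsv(lat_ase, file.path(outdir, "latitudinal_ase.tsv"))

wide <- tidyr::pivot_wider(lat_ase, id_cols = "gene",
                           names_from = "continent",
                           values_from = "ase_diff")
ok <- stats::complete.cases(wide)
sp <- spearman_correlation(wide$C1[ok], wide$C2[ok])
message(sprintf(
  "cross-continent correlation of latitudinal ASE differences: rho %.3f, p %.2g (%d genes)",
  sp$rho, sp$p, sum(ok)))

# robustness: repeat within reference-bias strata
for (st in c("toward_reference", "away", "neutral")) {
  genes_st <- intersect(wide$gene[ok],
                        bias$gene[bias$stratum == st])
  if (length(genes_st) >= 5) {
    sel <- wide$gene %in% genes_st
    sps <- spearman_correlation(wide$C1[sel], wide$C2[sel])
    message(sprintf("  stratum %-17s rho %.3f (%d genes)", st, sps$rho,
                    length(genes_st)))
  }
}

# enrichment of ASE among latitudinally differentiated genes
de <- lapply(c("C1", "C2"), function(cc)
  readr::read_tsv(file.path(outdir, paste0("latitudinal_de_", cc, ".tsv")),
                  show_col_types = FALSE))
both <- dplyr::inner_join(de[[1]], de[[2]], by = "gene",
                          suffix = c("_A", "_B"))
lat_genes <- both$gene[(both$p_A < 0.05 | both$p_B < 0.05) &
                         sign(both$log2_fold_A) == sign(both$log2_fold_B)]
universe <- intersect(ase$gene, both$gene)
enr <- ase_enrichment(intersect(lat_genes, universe),
                      intersect(sig, universe), universe)
message(sprintf(
  "ASE in %.0f%% of latitudinally differentiated genes vs %.0f%% of others (Fisher p %.2g, OR %.2f)",
  100 * enr$prop_ase_latitudinal, 100 * enr$prop_ase_other, enr$fisher$p,
  enr$fisher$odds_ratio))

summary <- list(
  cross_continent_spearman = sp,
  n_ase_significant = length(sig),
  n_latitudinal = length(lat_genes),
  enrichment = list(odds_ratio = enr$fisher$odds_ratio, p = enr$fisher$p,
                    prop_ase_latitudinal = enr$prop_ase_latitudinal,
                    prop_ase_other = enr$prop_ase_other))
jsonlite::write_json(summary, file.path(outdir, "clinal_summary.json"),
                     auto_unbox = TRUE, digits = NA)
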