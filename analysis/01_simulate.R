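#!/usr/bin/env Rscript
# Stage 1: generate the study-design dataset.
#
# Emulates the sampling design of the ASE study: 2 continents x 2 latitude
# classes, 13 wild isofemale-derived genotypes per population crossed to the
# reference strain, 4 genotypes per population with a biological replicate.
# Genes come in three classes: "cline" genes whose alternate CRE allele has
# latitude-structured frequencies (0.8 tropical / 0.2 temperate) and whose
# carrier status is coupled to total expression, "spectrum" genes with CRE
# variation at per-gene Beta-distributed frequencies but no cline, and
# "null" genes with no CRE variation. This mixture gives downstream stages
# every signal the analysis is designed to recover: ASE, a parallel cline in
# latitudinal ASE differences, ASE/expression coupling, a major/minor
# expression asymmetry, and ASE enrichment among latitudinally
# differentiated genes.

suppressMessages(library(clinase))

seed <- 1L
outdir <- "results"
dir.create(outdir, showWarnings = FALSE)

mix <- simulate_study_mixture(seed = seed, n_cline = 60, n_spectrum = 45,
                              n_null = 45)

write_allele_counts(mix$counts, file.path(outdir, "allele_counts.tsv"))
write_sample_metadata(mix$metadata, file.path(outdir, "metadata.tsv"))
readr::write_tsv(mix$classes, file.path(outdir, "gene_classes.tsv"))
readr::write_tsv(dplyr::bind_rows(lapply(mix$truths, `[[`, "genes")),
                 file.path(outdir, "truth_genes.tsv"))
readr::write_tsv(tibble::as_tibble(mix$expression, rownames = "gene"),
                 file.path(outdir, "total_expression_counts.tsv"))

message(sprintf("simulated %d genes (%s) x %d samples; %d allele-count rows",
                nrow(mix$classes),
                paste(table(mix$classes$class), collapse = "/"),
                nrow(mix$metadata), nrow(mix$counts)))
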