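#!/usr/bin/env Rscript
# Stage 3: high/low expression allele grouping.
#
# For every gene with significant ASE, sorts lines by replicate-summed log2
# wild/reference ratio, scores every ordered split with the mixed model plus
# a Group fixed effect, keeps the maximum-likelihood split, assigns the
# reference-CRE group (mean ratio closest to 0), and derives per-population
# high-allele frequencies, the major/minor designation and MAF.

suppressMessages(library(clinase))

outdir <- "results"
counts <- read_allele_counts(file.path(outdir, "allele_counts.tsv"))
metadata <- read_sample_metadata(file.path(outdir, "metadata.tsv"))
ase <- readr::read_tsv(file.path(outdir, "ase_tests.tsv"),
                       show_col_types = FALSE)

sig <- ase$gene[ase$significant]
message(sprintf("grouping %d ASE-significant genes", length(sig)))

grouping <- group_alleles(counts, genes = sig)
freqs <- allele_frequencies(grouping$line_calls, metadata)

readr::write_tsv(grouping$summary, file.path(outdir, "grouping_summary.tsv"))
readr::write_tsv(grouping$line_calls, file.path(outdir, "line_calls.tsv"))
readr::write_tsv(freqs$per_population,
                 file.path(outdir, "allele_freq_by_population.tsv"))
readr::write_tsv(freqs$per_gene, file.path(outdir, "allele_freq_genes.tsv"))

message(sprintf("wild allele is the high-expression allele for %d of %d genes",
                sum(grouping$summary$wild_allele == "high"),
                nrow(grouping$summary)))
message(sprintf("median ASE magnitude (log2 units): %.2f",
                stats::median(grouping$summary$ase_magnitude)))
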