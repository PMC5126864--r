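Package: clinase
Title: Allele-Specific Expression and Latitudinal Cline Analysis for Crossed Fly Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting cis-regulatory variation as
    allele-specific expression (ASE) in RNA-seq read counts from wild-by-reference
    crosses, and for relating that variation to latitudinal clines. Provides
    probabilistic SNP support thresholds and filters, per-gene wild/reference
    allele counting with read-conflict resolution, a binomial logit mixed model
    with genotype and observation-level random effects fitted by nested adaptive
    Gauss-Hermite quadrature, likelihood-ratio ASE tests with
    Benjamini-Hochberg FDR control, maximum-likelihood grouping of lines into
    high- and low-expression-allele groups, clinal concordance and enrichment
    statistics, and a synthetic-data generator that emulates the two-continent,
    temperate-versus-tropical study design with full ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
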