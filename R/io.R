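#' Read and write allele count tables and sample metadata
#'
#' Tab-separated text with a header; columns as produced by
#' [simulate_ase_dataset()] / [count_alleles_per_gene()]. `write_` functions
#' return the path invisibly; `read_`/`write_` round-trips are
#' content-identical for all supported columns.
#'
#' @param path file path.
#' @param x table to write.
#' @return a tibble (readers) or the path, invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_allele_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    wild_count = readr::col_integer(),
                    ref_count = readr::col_integer(),
                    .default = readr::col_character()))
}

#' @rdname table_io
#' @export
write_allele_counts <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_sample_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname table_io
#' @export
write_sample_metadata <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a sites-only SNP whitelist from VCF
#'
#' Parses a VCF (plain text) and returns its biallelic SNP records; INFO and
#' any genotype columns are ignored. Multi-allelic records and indels are
#' dropped.
#'
#' @param path VCF file path.
#' @return tibble: `chrom`, `pos` (1-based), `ref`, `alt`.
#' @examples
#' vcf <- system.file("extdata", "example_whitelist_synthetic.vcf",
#'                    package = "clinase")
#' read_snp_whitelist(vcf)
#' @export
read_snp_whitelist <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  out <- tibble::tibble(chrom = fx$CHROM, pos = as.integer(fx$POS),
                        ref = fx$REF, alt = fx$ALT)
  out[!is.na(out$alt) & !grepl(",", out$alt) &
        nchar(out$ref) == 1 & nchar(out$alt) == 1, , drop = FALSE]
}

#' Read gene intervals from BED or a minimal gene TSV
#'
#' BED input (no header, columns chrom/start/end/name) keeps the 0-based
#' half-open convention in the returned table; internal intersection converts
#' to 1-based inclusive coordinates, so a BED interval (chr2L, 0, 100) covers
#' 1-based positions 1-100. A TSV with header `gene, chrom, start, end` is
#' accepted with the same convention.
#'
#' @param path file path (`.bed` or `.tsv`).
#' @return tibble: `gene`, `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' bed <- system.file("extdata", "example_genes_synthetic.bed",
#'                    package = "clinase")
#' read_gene_intervals(bed)
#' @export
read_gene_intervals <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    b <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
    stopifnot(ncol(b) >= 3)
    name <- if (ncol(b) >= 4) as.character(b[[4]])
    else sprintf("interval%04d", seq_len(nrow(b)))
    tibble::tibble(gene = name, chrom = as.character(b[[1]]),
                   start = as.integer(b[[2]]), end = as.integer(b[[3]]))
  } else {
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      gene = readr::col_character(),
                      chrom = readr::col_character(),
                      start = readr::col_integer(),
                      end = readr::col_integer()))
  }
}

#' Read or write a simulation / pipeline configuration as JSON
#'
#' @param config a [simulation_config()] or [pipeline_config()] list.
#' @param path JSON file path.
#' @return the config (readers) or the path, invisibly (writers).
#' @export
write_config_json <- function(config, path) {
  cls <- class(config)
  x <- unclass(config)
  if (!is.null(x$cre_freq_by_population) &&
      !is.null(names(x$cre_freq_by_population)))
    x$cre_freq_by_population <- as.list(x$cre_freq_by_population)
  jsonlite::write_json(c(x, list(.class = cls)), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$.class
  x$.class <- NULL
  if (!is.null(x$cre_freq_by_population)) {
    if (!length(x$cre_freq_by_population))
      x["cre_freq_by_population"] <- list(NULL)
    else if (is.list(x$cre_freq_by_population))
      x$cre_freq_by_population <- unlist(x$cre_freq_by_population)
  }
  structure(x, class = cls)
}
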