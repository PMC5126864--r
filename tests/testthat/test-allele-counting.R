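test_that("SNP support threshold matches the exact binomial-tail oracle", {
  depths <- 0:150
  expect_equal(min_supporting_reads(depths),
               vapply(depths, oracle_min_support, numeric(1)))
  expect_identical(min_supporting_reads(15), 4L)
  expect_identical(min_supporting_reads(100), 7L)
  expect_identical(min_supporting_reads(0), 1L)
  m <- min_supporting_reads(0:400)
  expect_true(all(diff(m) >= 0))  # non-decreasing in depth
  expect_error(min_supporting_reads(10, error_rate = 0))
  expect_error(min_supporting_reads(10, alpha = 1))
})

make_pileup <- function(chrom = "chr1", pos, A = 0, C = 0, G = 0, T = 0) {
  tibble::tibble(chrom = chrom, pos = pos, count_A = A, count_C = C,
                 count_G = G, count_T = T)
}

test_that("SNP filters remove sites for the documented reasons", {
  iv <- tibble::tibble(gene = "g1", chrom = "chr1", start = 0L, end = 1000L)
  wl <- tibble::tibble(chrom = "chr1", pos = c(1L, 2L, 3L, 4L, 5L),
                       ref = "A", alt = "C")
  pu <- dplyr::bind_rows(
    make_pileup(pos = 1L, A = 7, C = 7),              # depth 14 -> depth filter
    make_pileup(pos = 2L, A = 10, C = 5, G = 3),      # three states
    make_pileup(pos = 3L, A = 17, C = 3),             # minor 3 < threshold 4
    make_pileup(pos = 4L, A = 10, C = 10),            # retained
    make_pileup(pos = 5L, A = 1000, C = 30))     # support 30 >= threshold 25
  res <- call_and_filter_snps(pu, iv, wl)
  expect_equal(res$snps$pos, c(4L, 5L))
  expect_equal(unname(res$removed[c("depth", "states", "support")]),
               c(1L, 1L, 1L))
  # empty whitelist wipes everything
  res0 <- call_and_filter_snps(pu, iv, wl[0, ])
  expect_equal(nrow(res0$snps), 0)
  # outside any gene
  iv2 <- tibble::tibble(gene = "g1", chrom = "chr1", start = 100L, end = 200L)
  res2 <- call_and_filter_snps(pu, iv2, wl)
  expect_equal(nrow(res2$snps), 0)
  expect_gte(res2$removed[["not_in_gene"]], 2)
  # whitelist allele mismatch removed
  wl3 <- wl; wl3$alt <- "G"
  res3 <- call_and_filter_snps(pu, iv, wl3)
  expect_equal(nrow(res3$snps), 0)
  # unknown chromosome reported, not fatal
  expect_warning(call_and_filter_snps(make_pileup(chrom = "chrX", pos = 1L,
                                                  A = 10, C = 10),
                                      iv, wl), "chrX")
})

test_that("filtering is monotone under whitelist restriction", {
  set.seed(10)
  pu <- simulate_pileups(500, c(15, 80), 0.3, 0.01, seed = 10)
  iv <- tibble::tibble(gene = "g1", chrom = "chr1", start = 0L, end = 600L)
  wl_full <- tibble::tibble(chrom = "chr1", pos = pu$pos, ref = "A",
                            alt = "C")
  wl_half <- wl_full[seq(1, nrow(wl_full), by = 2), ]
  full <- call_and_filter_snps(pu, iv, wl_full)$snps
  half <- call_and_filter_snps(pu, iv, wl_half)$snps
  expect_true(all(half$pos %in% full$pos))
  expect_lte(nrow(half), nrow(full))
})

asg <- function(sample, read, pos, allele) {
  tibble::tibble(sample = sample, read_id = read, chrom = "chr1",
                 pos = as.integer(pos), allele = allele)
}

test_that("conflicting reads are resolved by the configured rule", {
  # consistent read observed at two sites -> one wild call
  a <- dplyr::bind_rows(asg("s1", "r1", 101, "wild"),
                        asg("s1", "r1", 201, "wild"),
                        asg("s1", "r2", 101, "reference"))
  res <- resolve_conflicting_reads(a)
  expect_equal(nrow(res$calls), 2)
  expect_equal(sort(res$calls$allele), c("reference", "wild"))
  # conflicted read dropped under the default rule
  b <- dplyr::bind_rows(a, asg("s1", "r3", 101, "wild"),
                        asg("s1", "r3", 201, "reference"))
  resb <- resolve_conflicting_reads(b)
  expect_false("r3" %in% resb$calls$read_id)
  expect_equal(nrow(resb$removed_snps), 0)
  # drop_snp removes the high-conflict site and keeps the read
  conf <- dplyr::bind_rows(
    asg("s1", paste0("x", 1:10), 301, "wild"),
    asg("s1", paste0("x", 1:10), 401, "reference"))
  resc <- resolve_conflicting_reads(conf, rule = "drop_snp",
                                    snp_conflict_threshold = 0.5)
  expect_equal(sort(resc$removed_snps$pos), c(301L, 401L))
  # duplicate (read, site) rejected; empty input tolerated
  expect_error(resolve_conflicting_reads(dplyr::bind_rows(
    asg("s1", "r1", 1, "wild"), asg("s1", "r1", 1, "wild"))))
  expect_equal(nrow(resolve_conflicting_reads(a[0, ])$calls), 0)
})

test_that("per-gene allele counting is a direct tally with sparse rows", {
  iv <- tibble::tibble(gene = c("g1", "g2"), chrom = "chr1",
                       start = c(0L, 1000L), end = c(1000L, 2000L))
  md <- tibble::tibble(sample = "s1", genotype = "G1", replicate = "r1",
                       population = "P", latitude = "temperate",
                       continent = "C1")
  calls <- dplyr::bind_rows(
    asg("s1", paste0("w", 1:10), 500, "wild"),
    asg("s1", paste0("f", 1:6), 500, "reference"))
  tab <- count_alleles_per_gene(calls, iv, md)
  expect_equal(nrow(tab), 1)  # g2 has no row
  expect_equal(tab$wild_count, 10)
  expect_equal(tab$ref_count, 6)
  expect_equal(tab$wild_count + tab$ref_count, nrow(calls))  # conservation
  expect_error(count_alleles_per_gene(asg("s9", "r", 500, "wild"), iv, md),
               "s9")
})

test_that("error-free simulated reads reproduce the generator's counts", {
  cfg <- simulation_config(n_genes = 4, genotypes_per_population = 3,
                           replicated_genotypes_per_population = 1,
                           depth_mean = 40)
  sim <- simulate_ase_dataset(cfg, seed = 2)
  ra <- simulate_read_assignments(sim$counts, seed = 3)
  res <- resolve_conflicting_reads(ra$assignments)
  tab <- count_alleles_per_gene(res$calls, ra$intervals, sim$metadata)
  m <- dplyr::inner_join(sim$counts[, c("gene", "sample", "wild_count",
                                        "ref_count")],
                         tab[, c("gene", "sample", "wild_count",
                                 "ref_count")],
                         by = c("gene", "sample"))
  expect_equal(nrow(m), sum(sim$counts$wild_count + sim$counts$ref_count > 0))
  expect_equal(m$wild_count.x, m$wild_count.y)
  expect_equal(m$ref_count.x, m$ref_count.y)
})

test_that("reference bias summary pools counts and stratifies genes", {
  tab <- tibble::tibble(
    gene = c("g1", "g1", "g2", "g3"),
    sample = c("s1", "s2", "s1", "s1"),
    wild_count = c(10, 10, 40, 60), ref_count = c(10, 10, 60, 40))
  rb <- reference_bias_summary(tab)
  expect_equal(rb$per_gene$stratum[rb$per_gene$gene == "g1"], "neutral")
  expect_equal(rb$per_gene$stratum[rb$per_gene$gene == "g2"],
               "toward_reference")
  expect_equal(rb$per_gene$stratum[rb$per_gene$gene == "g3"], "away")
  expect_true(all(rb$per_sample$ref_prop >= 0 & rb$per_sample$ref_prop <= 1))
  one <- reference_bias_summary(tab[tab$sample == "s1", ])
  expect_equal(one$overall_mean_ref_prop,
               sum(c(10, 60, 40)) / sum(c(20, 100, 100)))
  expect_error(reference_bias_summary(tab[0, ]))
})
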