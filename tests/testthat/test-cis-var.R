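test_that("per-sample aFC follows the pseudocount formula", {
  expect_equal(sample_afc(31, 15), 1.0)          # log2(32/16)
  expect_equal(sample_afc(0, 0), 0.0)
  for (k in c(0, 1, 5, 100)) expect_equal(sample_afc(k, k), 0.0)
  expect_equal(sample_afc(3, 99), log2(4 / 100))
})

test_that("haplotype orientation follows the VCF-hap1 = HAP_A contract", {
  # GT 0|1 with cell (hapA=10, hapB=30): alt allele on hap2 -> hapB
  o1 <- orient_haplotype_counts(0L, 1L, 10L, 30L)
  expect_equal(o1$genotype_class, "het")
  expect_equal(c(o1$alt_hap, o1$ref_hap), c(30L, 10L))
  # GT 1|0: swapped
  o2 <- orient_haplotype_counts(1L, 0L, 10L, 30L)
  expect_equal(c(o2$alt_hap, o2$ref_hap), c(10L, 30L))
  # homozygotes: unoriented
  o3 <- orient_haplotype_counts(1L, 1L, 10L, 30L)
  expect_equal(o3$genotype_class, "hom_alt")
  expect_true(is.na(o3$alt_hap))
  o4 <- orient_haplotype_counts(0L, 1L, 10L, 30L, phased = FALSE)
  expect_equal(o4$genotype_class, "unphased")
})

test_that("variant summaries: median, skips, dedup and degenerate inputs", {
  gt <- tiny_gt()
  mat <- tiny_mat()
  res <- run_cis_var(tibble::tibble(variant_id = c("v1", "v1", "vX"),
                                    gene_id = c("G1", "G1", "G9")),
                     gt, mat, min_coverage = 8, seed = 2) |>
    suppressWarnings()
  expect_equal(nrow(res$summary), 1L)
  expect_equal(res$skipped$reason, "variant_not_in_vcf")
  # S1: 0|1 cell (10,30) -> afc log2(31/11); S2: 1|0 -> log2(11/31)
  s <- res$summary
  expect_equal(s$n_het, 2L)
  expect_equal(s$n_hom, 1L)
  expect_equal(s$median_afc, median(c(log2(31 / 11), log2(11 / 31))))
  smp <- tidy(res, "samples")
  expect_equal(nrow(smp), 3L)  # all underlying rows emitted

  # zero usable samples: statistics absent, not an error
  mat0 <- hap_matrix(tibble::tibble(gene_id = "G1", sample_id = "S9",
                                    hapA = 50L, hapB = 50L), TRUE)
  res0 <- run_cis_var(tibble::tibble(variant_id = "v1", gene_id = "G1"),
                      gt, mat0, seed = 2)
  expect_equal(res0$summary$n_het, 0L)
  expect_true(is.na(res0$summary$median_afc))
  expect_true(is.na(res0$summary$ranksum_p))
})

test_that("odd-sample median is exact", {
  gt <- haploAE:::new_phased_gt(tibble::tibble(
    variant_id = "v", chrom = "chr1", pos = 1L, ref = "A", alt = "G",
    sample_id = c("a", "b", "c"), h1 = 0L, h2 = 1L, phased = TRUE))
  # counts giving aFC 0.8, 1.0, 1.3 via alt = 2^afc*(ref+1)-1
  ref <- c(19L, 15L, 9L)
  alt <- as.integer(round(2^c(0.8, 1.0, 1.3) * (ref + 1) - 1))
  mat <- hap_matrix(tibble::tibble(gene_id = "G", sample_id = c("a", "b", "c"),
                                   hapA = ref, hapB = alt), TRUE)
  res <- run_cis_var(tibble::tibble(variant_id = "v", gene_id = "G"),
                     gt, mat, seed = 1)
  expect_equal(res$summary$median_afc, sample_afc(alt[2], ref[2]))
})

test_that("results are deterministic and invariant to sample order", {
  sim <- simulate_cohort("single-eqtl",
                         sim_config(n_samples = 60, n_genes = 2, seed = 9))
  r1 <- run_cis_var(sim$eqtl_list, sim$genotypes, sim$matrices[[1]], seed = 5)
  r2 <- run_cis_var(sim$eqtl_list, sim$genotypes, sim$matrices[[1]], seed = 5)
  expect_identical(r1$summary, r2$summary)

  perm <- sample(nrow(sim$genotypes))
  gt_p <- haploAE:::new_phased_gt(sim$genotypes[perm, ])
  mat_p <- hap_matrix(tibble::as_tibble(sim$matrices[[1]])[
    sample(nrow(sim$matrices[[1]])), ], gw_phased = TRUE)
  r3 <- run_cis_var(sim$eqtl_list, gt_p, mat_p, seed = 5)
  expect_equal(r3$summary, r1$summary)
})

test_that("swapping ref/alt labels negates every het aFC and the median", {
  sim <- simulate_cohort("single-eqtl",
                         sim_config(n_samples = 80, n_genes = 2, seed = 13))
  gt <- sim$genotypes
  r1 <- run_cis_var(sim$eqtl_list, gt, sim$matrices[[1]], seed = 3)
  gt_swap <- gt
  gt_swap$h1 <- 1L - gt$h1
  gt_swap$h2 <- 1L - gt$h2
  tmp <- gt_swap$ref; gt_swap$ref <- gt_swap$alt; gt_swap$alt <- tmp
  r2 <- run_cis_var(sim$eqtl_list, haploAE:::new_phased_gt(gt_swap),
                    sim$matrices[[1]], seed = 3)
  het1 <- dplyr::filter(r1$samples, genotype_class == "het")
  het2 <- dplyr::filter(r2$samples, genotype_class == "het")
  expect_equal(het2$afc, -het1$afc)
  expect_equal(r2$summary$median_afc, -r1$summary$median_afc)
})

test_that("balanced het and hom samples give no ranksum excess", {
  gt <- haploAE:::new_phased_gt(tibble::tibble(
    variant_id = "v", chrom = "chr1", pos = 1L, ref = "A", alt = "G",
    sample_id = sprintf("s%d", 1:6),
    h1 = c(0L, 0L, 0L, 0L, 1L, 1L), h2 = c(1L, 1L, 1L, 0L, 1L, 1L),
    phased = TRUE))
  mat <- hap_matrix(tibble::tibble(gene_id = "G",
                                   sample_id = sprintf("s%d", 1:6),
                                   hapA = 20L, hapB = 20L), TRUE)
  res <- suppressWarnings(
    run_cis_var(tibble::tibble(variant_id = "v", gene_id = "G"),
                gt, mat, seed = 1))
  expect_gte(res$summary$ranksum_p, 0.5)
})

test_that("per-sample intervals contain the point estimate", {
  sim <- simulate_cohort("single-eqtl",
                         sim_config(n_samples = 50, n_genes = 1, seed = 23))
  res <- run_cis_var(sim$eqtl_list, sim$genotypes, sim$matrices[[1]],
                     seed = 23)
  het <- dplyr::filter(res$samples, genotype_class == "het", pass)
  expect_true(all(het$afc_lo <= het$afc + 1e-9))
  expect_true(all(het$afc_hi >= het$afc - 1e-9))
  s <- res$summary
  expect_true(s$median_afc_lo <= s$median_afc &&
                s$median_afc <= s$median_afc_hi)
})
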