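test_that("simulation is seed-deterministic and preserves the global RNG", {
  cfg <- sim_config(n_samples = 20, n_genes = 5, seed = 7)
  s1 <- simulate_cohort("single-eqtl", cfg)
  s2 <- simulate_cohort("single-eqtl", cfg)
  expect_identical(tibble::as_tibble(s1$matrices[[1]]),
                   tibble::as_tibble(s2$matrices[[1]]))
  expect_identical(s1$genotypes, s2$genotypes)

  set.seed(99); a <- runif(3)
  set.seed(99); invisible(simulate_cohort("null", cfg)); b <- runif(3)
  expect_identical(a, b)

  s3 <- simulate_cohort("single-eqtl",
                        sim_config(n_samples = 20, n_genes = 5, seed = 8))
  expect_false(identical(tibble::as_tibble(s3$matrices[[1]]),
                         tibble::as_tibble(s1$matrices[[1]])))
})

test_that("genotypes follow Hardy-Weinberg at the requested frequency", {
  vars <- tibble::tibble(variant_id = sprintf("v%d", 1:5), chrom = "chr1",
                         pos = 1:5 * 100L, ref = "A", alt = "G",
                         maf = c(0, 0, 0.3, 0.3, 0.3))
  set.seed(11)
  gt <- simulate_genotypes(vars, 2000)
  # maf 0: every haplotype carries the reference allele
  z <- dplyr::filter(gt, variant_id %in% c("v1", "v2"))
  expect_true(all(z$h1 == 0L & z$h2 == 0L))
  expect_true(all(gt$phased))
  # maf 0.3: het fraction approx 2pq = 0.42
  h <- dplyr::filter(gt, variant_id == "v3")
  # tolerances are ~4 Monte-Carlo standard errors at n = 2000
  expect_equal(mean(h$h1 + h$h2 == 1), 2 * 0.3 * 0.7, tolerance = 0.11)
  expect_equal(mean(c(h$h1, h$h2)), 0.3, tolerance = 0.1)
})

test_that("expected ratios encode additive log2 haplotype effects", {
  vars <- tibble::tibble(variant_id = "v", chrom = "chr1", pos = 1L,
                         ref = "A", alt = "G", maf = 0.5,
                         gene_id = "G", effect = 1)
  gt <- haploAE:::new_phased_gt(tibble::tibble(
    variant_id = "v", chrom = "chr1", pos = 1L, ref = "A", alt = "G",
    sample_id = c("het10", "het01", "homref", "homalt"),
    h1 = c(1L, 0L, 0L, 1L), h2 = c(0L, 1L, 0L, 1L), phased = TRUE))
  r <- expected_hap_ratios(gt, vars)
  get <- function(s) r$p_hapA[r$sample_id == s]
  expect_equal(get("het10"), 2 / 3)   # alt on hap1 doubles hap1 expression
  expect_equal(get("het01"), 1 / 3)
  expect_equal(get("homref"), 0.5)
  expect_equal(get("homalt"), 0.5)
  # effect 0 everywhere -> flat 0.5
  r0 <- expected_hap_ratios(gt, dplyr::mutate(vars, effect = 0))
  expect_true(all(r0$p_hapA == 0.5))
})

test_that("overdispersion widens allelic fractions; rho = 0 is binomial", {
  ratios <- tibble::tibble(gene_id = "G", sample_id = sprintf("s%d", 1:4000),
                           p_hapA = 0.5)
  cfg0 <- sim_config(n_samples = 4000, n_genes = 1, rho = 0,
                     mean_coverage = 200, coverage_size = 1e6, seed = 1)
  cfg1 <- sim_config(n_samples = 4000, n_genes = 1, rho = 0.1,
                     mean_coverage = 200, coverage_size = 1e6, seed = 1)
  set.seed(2); m0 <- simulate_hap_counts(ratios, cfg0)
  set.seed(2); m1 <- simulate_hap_counts(ratios, cfg1)
  frac <- function(m) m$hapA / (m$hapA + m$hapB)
  # binomial sd of the fraction at n ~ 200, p = 0.5
  expect_equal(sd(frac(m0)), sqrt(0.25 / 200), tolerance = 0.1)
  expect_gt(var(frac(m1)), 2 * var(frac(m0)))
})

test_that("plug-in aFC matches the generative effect at extreme coverage", {
  cfg <- sim_config(n_samples = 400, n_genes = 1, afc = 1.5,
                    mean_coverage = 50000, coverage_size = 1e6, seed = 3)
  sim <- simulate_cohort("single-eqtl", cfg)
  res <- run_cis_var(sim$eqtl_list, sim$genotypes, sim$matrices[[1]],
                     seed = 3)
  expect_equal(res$summary$median_afc, 1.5, tolerance = 0.01)
})

test_that("unknown scenarios are rejected", {
  expect_error(simulate_cohort("bogus", sim_config(seed = 1)))
})

test_that("injected genotyping errors look like noise-only heterozygotes", {
  cfg <- sim_config(n_samples = 100, n_genes = 40, error_rate = 0.05,
                    min_site_coverage = 30, seed = 21)
  sim <- simulate_cohort("genotype-errors", cfg)
  expect_gt(nrow(sim$truth$error_sites), 0)
  joined <- dplyr::inner_join(sim$snp_counts, sim$snp_truth,
                              by = c("variant_id", "sample_id"))
  err <- dplyr::filter(joined, injected_error)
  minor <- pmin(err$ref_count, err$alt_count)
  cov <- err$ref_count + err$alt_count
  # minor reads are Binomial(cov, epsilon): mean near epsilon, far below 0.5
  expect_lt(mean(minor / cov), 0.02)
  true_het <- dplyr::filter(joined, !injected_error)
  expect_gt(mean(pmin(true_het$ref_count, true_het$alt_count) /
                   (true_het$ref_count + true_het$alt_count)), 0.3)
  # coverage floor honoured
  expect_true(all(sim$snp_counts$ref_count + sim$snp_counts$alt_count >= 30))
})

test_that("allele-pair reference bias is recoverable from simulated counts", {
  n <- 8000
  gt <- haploAE:::new_phased_gt(tibble::tibble(
    variant_id = sprintf("v%d", seq_len(n)), chrom = "chr1",
    pos = seq_len(n), ref = "A", alt = "G",
    sample_id = "S1", h1 = 0L, h2 = 1L, phased = TRUE))
  vars <- dplyr::distinct(gt, variant_id, chrom, pos, ref, alt) |>
    dplyr::mutate(gene_id = "G", effect = 0, role = "coding", maf = 0.5)
  ratios <- expected_hap_ratios(gt, vars)
  cfg <- sim_config(n_samples = 1, n_genes = 1, mean_coverage = 120,
                    coverage_size = 20, seed = 1)
  set.seed(31)
  snp <- simulate_snp_counts(gt, vars, ratios, cfg,
                             bias_table = tibble::tibble(ref = "A", alt = "G",
                                                         p0 = 0.52))
  nr <- estimate_null_ratios(snp$records, min_sites = 200)
  expect_equal(nr$p0[nr$ref == "A" & nr$alt == "G"], 0.52, tolerance = 0.021)
})

test_that("cohorts round-trip through the on-disk formats", {
  sim <- simulate_cohort("single-eqtl",
                         sim_config(n_samples = 8, n_genes = 3, seed = 5))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  mat <- read_hap_matrix(file.path(dir, "matrix_tissue1.gw_phased.txt.gz"))
  expect_true(is_gw_phased(mat))
  key <- function(m) dplyr::arrange(tibble::as_tibble(m), gene_id, sample_id)
  expect_equal(key(mat), key(sim$matrices[[1]]))
  gt <- read_phased_vcf(file.path(dir, "sim.vcf.gz"))
  cols <- c("variant_id", "sample_id", "h1", "h2", "phased")
  expect_equal(dplyr::arrange(tibble::as_tibble(gt[cols]),
                              variant_id, sample_id),
               dplyr::arrange(tibble::as_tibble(sim$genotypes[cols]),
                              variant_id, sample_id))
  genes <- read_gene_bed(file.path(dir, "genes.bed"))
  expect_equal(genes$gene_id, sim$genes$gene_id)
  expect_equal(genes$tss, sim$genes$tss)
})
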