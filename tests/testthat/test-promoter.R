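test_that("MAF binning applies the lower-inclusive upper-exclusive rule", {
  spec <- maf_bin_spec()
  expect_equal(spec$bin[assign_maf_bin(0.05)], "bin_0.10_0.05")  # >= lower
  expect_equal(spec$bin[assign_maf_bin(0.004)], "bin_0.005_0")
  expect_equal(spec$bin[assign_maf_bin(0.50)], "bin_0.50_0.10")  # top closed
  expect_equal(spec$bin[assign_maf_bin(0.0999)], "bin_0.10_0.05")
  expect_equal(spec$bin[assign_maf_bin(0.10)], "bin_0.50_0.10")
  expect_error(assign_maf_bin(0.6), "minor allele")
  expect_error(assign_maf_bin(0), "positive")
  # every MAF in (0, 0.5] maps to exactly one bin
  maf <- seq(0.0001, 0.5, by = 0.0037)
  expect_false(any(is.na(assign_maf_bin(maf))))
})

test_that("design rows bin het promoter variants and median |aFC| over tissues", {
  genes <- tiny_genes()  # G1 + strand tss(1-based) 1000; G2 - strand tss 6000
  vars <- tibble::tibble(
    variant_id = c("c1", "c2", "r1", "g2up", "g2down"),
    chrom = "chr1", pos = c(500L, 600L, 700L, 5000L, 7000L),
    ref = "A", alt = "G")
  gt <- haploAE:::new_phased_gt(
    tidyr::expand_grid(vars, sample_id = c("S1", "S2")) |>
      dplyr::mutate(h1 = ifelse(sample_id == "S1", 0L, 0L),
                    h2 = ifelse(sample_id == "S1", 1L, 0L),
                    phased = TRUE))
  freqs <- tibble::tibble(variant_id = vars$variant_id,
                          maf = c(0.3, 0.3, 0.002, 0.3, 0.3))
  mats <- list(
    hap_matrix(tibble::tibble(gene_id = c("G1", "G2"), sample_id = "S1",
                              hapA = c(12L, 10L), hapB = c(4L, 10L)), TRUE),
    hap_matrix(tibble::tibble(gene_id = "G1", sample_id = "S1",
                              hapA = 20L, hapB = 20L), TRUE))
  d <- build_promoter_design(mats, gt, genes, allele_freqs = freqs)
  r1 <- d[d$gene_id == "G1" & d$sample_id == "S1", ]
  expect_equal(r1$bin_0.50_0.10, 2L)   # two common het variants
  expect_equal(r1$bin_0.005_0, 1L)     # one rare het variant
  expect_equal(r1$bin_0.05_0.01, 0L)
  expect_equal(r1$y, median(c(abs(log2(13 / 5)), 0)))
  # minus-strand gene: upstream means positions >= TSS
  r2 <- d[d$gene_id == "G2" & d$sample_id == "S1", ]
  expect_equal(r2$bin_0.50_0.10, 1L)   # 7000 in [6000, 15999]; 5000 not
  # S2 has no het variants but AE data is absent -> no row for S2
  expect_equal(nrow(d[d$sample_id == "S2", ]), 0L)
})

test_that("rows with zero het promoter variants are retained", {
  genes <- tiny_genes()
  gt <- haploAE:::new_phased_gt(tibble::tibble(
    variant_id = "far", chrom = "chr1", pos = 900000L, ref = "A", alt = "G",
    sample_id = "S1", h1 = 0L, h2 = 1L, phased = TRUE))
  mats <- hap_matrix(tibble::tibble(gene_id = "G1", sample_id = "S1",
                                    hapA = 30L, hapB = 10L), TRUE)
  d <- build_promoter_design(mats, gt, genes)
  expect_equal(nrow(d), 1L)
  expect_equal(sum(d[grep("^bin_", names(d))]), 0L)
})

test_that("noise-free linear responses are recovered to machine precision", {
  set.seed(101)
  spec <- maf_bin_spec()
  n <- 60
  design <- tibble::as_tibble(setNames(
    lapply(seq_len(5), function(i) rpois(n, 1.2)), spec$bin))
  design$y <- 0.1 + 0.5 * design$bin_0.005_0
  # an exact fit triggers lm's "essentially perfect fit" note; expected here
  fit <- suppressWarnings(fit_promoter_model(design))
  est <- suppressWarnings(tidy(fit))
  expect_equal(est$estimate[est$term == "(Intercept)"], 0.1,
               tolerance = 1e-10)
  expect_equal(est$estimate[est$term == "bin_0.005_0"], 0.5,
               tolerance = 1e-10)
  expect_equal(max(abs(est$estimate[!est$term %in%
                                      c("(Intercept)", "bin_0.005_0")])),
               0, tolerance = 1e-10)
  # CI contains the estimate
  expect_true(all(est$conf_low <= est$estimate + 1e-12 &
                    est$estimate <= est$conf_high + 1e-12))
})

test_that("rank deficiency and undersized designs are rejected by name", {
  spec <- maf_bin_spec()
  set.seed(5)
  design <- tibble::as_tibble(setNames(
    lapply(seq_len(5), function(i) rpois(30, 1)), spec$bin))
  design$bin_0.005_0 <- design$bin_0.50_0.10  # collinear
  design$y <- rnorm(30)
  expect_error(fit_promoter_model(design), "bin_0.005_0")
  expect_error(fit_promoter_model(design[1:4, ]), "too few")
})

test_that("duplicating the dataset keeps estimates and narrows intervals", {
  sim <- simulate_cohort("rare-promoter",
                         sim_config(n_samples = 100, n_genes = 5, seed = 41))
  f1 <- fit_promoter_model(sim$design)
  f2 <- fit_promoter_model(dplyr::bind_rows(sim$design, sim$design))
  expect_equal(tidy(f2)$estimate, tidy(f1)$estimate, tolerance = 1e-10)
  expect_true(all(tidy(f2)$conf_high - tidy(f2)$conf_low <
                    tidy(f1)$conf_high - tidy(f1)$conf_low))
  # permutation equivariance
  set.seed(1)
  f3 <- fit_promoter_model(sim$design[sample(nrow(sim$design)), ])
  expect_equal(tidy(f3)$estimate, tidy(f1)$estimate, tolerance = 1e-12)
})

test_that("confidence intervals achieve near-nominal coverage", {
  set.seed(77)
  hits <- 0L
  reps <- 200
  for (r in seq_len(reps)) {
    x <- rpois(80, 1.5)
    y <- 0.2 + 0.3 * x + rnorm(80, sd = 0.5)
    fit <- fit_promoter_model(tibble::tibble(bin_0.50_0.10 = x, y = y))
    ci <- tidy(fit)
    lo <- ci$conf_low[ci$term == "bin_0.50_0.10"]
    hi <- ci$conf_high[ci$term == "bin_0.50_0.10"]
    hits <- hits + (lo <= 0.3 && 0.3 <= hi)
  }
  expect_gt(hits / reps, 0.90)
  expect_lt(hits / reps, 0.99)
})
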