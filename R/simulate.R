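#' Simulation configuration for a synthetic AE cohort
#'
#' Collects the generative parameters of the synthetic cohort: a panmictic
#' population in Hardy-Weinberg equilibrium, one or more cis-regulatory
#' variants per gene acting additively on the log2 haplotype expression
#' scale, gene-level total coverage drawn negative-binomial, haplotype A
#' counts drawn beta-binomial around the expected allelic ratio (plain
#' binomial at `rho = 0`), per-read sequencing noise, and optional injected
#' genotyping errors (homozygous sites mislabeled heterozygous whose
#' minor-allele reads are pure noise).
#'
#' @param n_samples Cohort size.
#' @param n_genes Number of genes.
#' @param n_tissues Number of tissues (matrices) to emit.
#' @param maf Minor allele frequency of regulatory/coding variants (variants
#'   below 0.01 are not emitted as expression-measuring sites, matching the
#'   minimum haplotype MAF used by upstream quantification).
#' @param afc True regulatory effect size alpha, in log2 units.
#' @param mean_coverage,coverage_size Negative-binomial mean and size of
#'   per-cell total haplotypic coverage.
#' @param rho Beta-binomial overdispersion of allelic counts in `[0, 1)`;
#'   0 reduces to binomial.
#' @param epsilon Per-read sequencing noise probability.
#' @param error_rate Fraction of homozygous coding sites mislabeled as
#'   heterozygous.
#' @param n_coding_snps Heterozygous-measurable coding SNPs per gene for the
#'   SNP-level table.
#' @param min_site_coverage Floor applied to per-site coverage draws.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200, n_genes = 50, n_tissues = 1,
                       maf = 0.3, afc = 1, mean_coverage = 100,
                       coverage_size = 5, rho = 0, epsilon = 0.005,
                       error_rate = 0, n_coding_snps = 2,
                       min_site_coverage = 0, seed = 1L) {
  stopifnot(n_samples >= 1, n_genes >= 1, n_tissues >= 1,
            maf >= 0, maf <= 0.5, rho >= 0, rho < 1,
            epsilon > 0, epsilon < 0.5, error_rate >= 0, error_rate <= 1,
            mean_coverage > 0, coverage_size > 0)
  if (is.null(seed)) abort("a seed is mandatory for reproducible simulation")
  structure(as.list(environment()), class = "sim_config")
}

with_preserved_seed <- function(code) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  force(code)
}

rbetabinom <- function(n, size, p, rho) {
  if (rho == 0) return(rbinom(n, size, p))
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

#' Simulate phased genotypes under Hardy-Weinberg equilibrium
#'
#' Each haplotype allele is drawn i.i.d. Bernoulli at the variant's allele
#' frequency; all genotypes are phased.
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf`.
#' @param n_samples Number of individuals.
#' @param sample_ids Optional sample names (default `S001`, ...).
#' @return A `phased_gt` tibble.
#' @export
simulate_genotypes <- function(variants, n_samples,
                               sample_ids = NULL) {
  sample_ids <- sample_ids %||%
    sprintf("S%03d", seq_len(n_samples))
  nv <- nrow(variants)
  h1 <- matrix(rbinom(nv * n_samples, 1, rep(variants$maf, n_samples)),
               nrow = nv)
  h2 <- matrix(rbinom(nv * n_samples, 1, rep(variants$maf, n_samples)),
               nrow = nv)
  new_phased_gt(tibble(
    variant_id = rep(variants$variant_id, n_samples),
    chrom = rep(variants$chrom, n_samples),
    pos = rep(variants$pos, n_samples),
    ref = rep(variants$ref, n_samples),
    alt = rep(variants$alt, n_samples),
    sample_id = rep(sample_ids, each = nv),
    h1 = as.integer(h1), h2 = as.integer(h2),
    phased = TRUE))
}

#' Expected haplotype-A read fraction per gene and sample
#'
#' Regulatory alleles act additively on the log2 haplotype expression scale:
#' with summed per-haplotype effects `A1` and `A2`, the expected fraction of
#' the gene's reads from haplotype 1 (HAP_A) is `2^A1 / (2^A1 + 2^A2)`.
#'
#' @param gt A `phased_gt`.
#' @param variants Variant table with `gene_id` and `effect` (log2 units;
#'   non-regulatory variants have effect 0).
#' @return Tibble `gene_id`, `sample_id`, `p_hapA`.
#' @export
expected_hap_ratios <- function(gt, variants) {
  reg <- filter(variants, .data$effect != 0)
  base <- distinct(gt, .data$sample_id) |>
    tidyr::expand_grid(gene_id = unique(variants$gene_id))
  if (nrow(reg) == 0) {
    return(mutate(base, p_hapA = 0.5))
  }
  eff <- gt |>
    inner_join(select(reg, "variant_id", "gene_id", "effect"),
               by = "variant_id") |>
    group_by(.data$gene_id, .data$sample_id) |>
    summarise(a1 = sum(.data$effect * .data$h1),
              a2 = sum(.data$effect * .data$h2), .groups = "drop") |>
    mutate(p_hapA = 2^.data$a1 / (2^.data$a1 + 2^.data$a2))
  base |>
    left_join(select(eff, "gene_id", "sample_id", "p_hapA"),
              by = c("gene_id", "sample_id")) |>
    mutate(p_hapA = ifelse(is.na(.data$p_hapA), 0.5, .data$p_hapA))
}

#' Simulate a haplotypic expression matrix
#'
#' @param ratios Expected ratios from [expected_hap_ratios()].
#' @param config A [sim_config()].
#' @return A genome-wide-phased `hap_matrix`.
#' @export
simulate_hap_counts <- function(ratios, config) {
  n <- nrow(ratios)
  total <- rnbinom(n, size = config$coverage_size, mu = config$mean_coverage)
  hapA <- rbetabinom(n, total, ratios$p_hapA, config$rho)
  hap_matrix(tibble(gene_id = ratios$gene_id, sample_id = ratios$sample_id,
                    hapA = as.integer(hapA),
                    hapB = as.integer(total - hapA)),
             gw_phased = TRUE)
}

#' Simulate a SNP-level allele-count table
#'
#' Emits one record per heterozygous coding site per sample: site coverage
#' drawn negative-binomial (floored at `min_site_coverage`), reference reads
#' binomial around the haplotype ratio of the haplotype carrying the
#' reference allele, shifted on the logit scale by any allele-pair reference
#' bias, `other` reads binomial at the noise rate. A fraction `error_rate`
#' of homozygous sites is additionally mislabeled heterozygous with
#' minor-allele reads drawn from noise alone.
#'
#' @param gt A `phased_gt`.
#' @param variants Variant table; rows with `role == "coding"` are measured.
#' @param ratios Expected ratios from [expected_hap_ratios()].
#' @param config A [sim_config()].
#' @param bias_table Optional tibble `ref`, `alt`, `p0` of reference-bias
#'   null ratios (default: unbiased 0.5 everywhere).
#' @return List with `records` (SNP allele-count tibble with `sample_id`,
#'   `tissue_id`, `true_het` and `injected_error` truth columns dropped into
#'   `truth`) and `truth` (tibble of injected-error site keys).
#' @export
simulate_snp_counts <- function(gt, variants, ratios, config,
                                bias_table = NULL) {
  coding <- filter(variants, .data$role == "coding")
  df <- gt |>
    inner_join(select(coding, "variant_id", "gene_id"), by = "variant_id") |>
    left_join(ratios, by = c("gene_id", "sample_id"))
  het <- !is.na(df$h1) & !is.na(df$h2) & df$h1 + df$h2 == 1
  hom <- !is.na(df$h1) & !is.na(df$h2) & df$h1 == df$h2
  err <- hom & runif(nrow(df)) < config$error_rate
  keep <- het | err
  df <- df[keep, , drop = FALSE]
  is_err <- err[keep]

  n <- nrow(df)
  cov <- pmax(rnbinom(n, size = config$coverage_size,
                      mu = config$mean_coverage),
              config$min_site_coverage)
  cov <- pmax(cov, 1L)
  # reference allele sits on haplotype 1 iff h1 == 0 (true hets)
  p_ref_raw <- ifelse(df$h1 == 0, df$p_hapA, 1 - df$p_hapA)
  if (!is.null(bias_table)) {
    df2 <- left_join(df, bias_table, by = c("ref", "alt"))
    p0 <- ifelse(is.na(df2$p0), 0.5, df2$p0)
  } else {
    p0 <- rep(0.5, n)
  }
  p_ref <- stats::plogis(stats::qlogis(p_ref_raw) + stats::qlogis(p0))
  ref_count <- rbinom(n, cov, p_ref)
  alt_count <- cov - ref_count
  # injected errors: the false minor allele is supported by noise reads only
  if (any(is_err)) {
    noise <- rbinom(sum(is_err), cov[is_err], config$epsilon)
    maj_is_ref <- df$h1[is_err] == 0  # hom-ref mislabeled het
    ref_count[is_err] <- ifelse(maj_is_ref, cov[is_err] - noise, noise)
    alt_count[is_err] <- cov[is_err] - ref_count[is_err]
  }
  other_count <- rbinom(n, cov, config$epsilon)

  records <- tibble(
    chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
    variant_id = df$variant_id, sample_id = df$sample_id,
    tissue_id = "tissue1", gene_id = df$gene_id,
    ref_count = as.integer(ref_count), alt_count = as.integer(alt_count),
    other_count = as.integer(other_count))
  truth <- tibble(variant_id = df$variant_id, sample_id = df$sample_id,
                  injected_error = is_err)
  list(records = records, truth = truth)
}

sim_ref_alt <- function(n) {
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
  tibble(ref = ref, alt = unname(alt))
}

sim_gene_table <- function(n_genes, body_len = 50000L, spacing = 1000000L) {
  start <- spacing * seq_len(n_genes)
  tibble(chrom = "chr1", start = start, end = start + body_len,
         gene_id = sprintf("GENE%04d", seq_len(n_genes)),
         gene_type = "protein_coding", strand = "+") |>
    gene_annotation()
}

# per-bin promoter-variant layout used by the rare-promoter scenario:
# MAFs at (geometric-ish) bin midpoints, several variants per bin so the
# rare bins still vary across individuals
promoter_bin_mafs <- c(0.22, 0.07, 0.022, 0.007, 0.002)
promoter_bin_effects <- c(0.05, 0.08, 0.12, 0.2, 0.3)

#' Simulate a synthetic AE cohort under a named scenario
#'
#' Scenario presets covering the statistical structure the analysis methods
#' assume:
#' \describe{
#'   \item{`null`}{no regulatory effects anywhere; calibration input for the
#'     imbalance and rank-sum tests.}
#'   \item{`single-eqtl`}{one cis-eQTL per gene with true effect `afc`;
#'     effect-size recovery input.}
#'   \item{`rare-promoter`}{promoter-proximal variants in the five MAF bins
#'     with per-variant effects 0.05/0.08/0.12/0.2/0.3 (common to rare);
#'     the response is generated under the linear-Gaussian model the
#'     promoter fit assumes (`y = 0.1 + X beta + N(0, 0.5^2)`).}
#'   \item{`genotype-errors`}{no effects; a fraction of homozygous coding
#'     sites mislabeled heterozygous, minor reads from noise alone.}
#'   \item{`eqtl-mask`}{every gene driven by one strong regulatory variant;
#'     a fraction `listed_frac` of drivers appears in the emitted eQTL list,
#'     the rest are unlisted (rare-variant stand-ins) — input for the
#'     eQTL-heterozygote masking analysis.}
#' }
#'
#' @param scenario One of the preset names above.
#' @param config A [sim_config()]; scenario-appropriate defaults are used
#'   for fields the preset fixes.
#' @param listed_frac For `eqtl-mask`: fraction of genes whose driver is in
#'   the emitted eQTL list (default 0.8).
#' @param promoter_n_per_bin For `rare-promoter`: promoter variants per MAF
#'   bin per gene (default 4).
#' @param promoter_sd For `rare-promoter`: Gaussian noise sd on `y`
#'   (default 0.5).
#' @param promoter_intercept For `rare-promoter`: baseline absolute aFC
#'   (default 0.1).
#' @return A list of class `ae_sim` with elements `config`, `genes`,
#'   `variants`, `genotypes`, `matrices` (list of `hap_matrix`, one per
#'   tissue), `eqtl_list`, `eqtl_table` (mask input; `eqtl-mask` only),
#'   `snp_counts` and `snp_truth` (scenarios with coding sites), `design`
#'   and `truth`.
#' @export
simulate_cohort <- function(scenario = c("null", "single-eqtl",
                                         "rare-promoter", "genotype-errors",
                                         "eqtl-mask"),
                            config = sim_config(), listed_frac = 0.8,
                            promoter_n_per_bin = 4, promoter_sd = 0.5,
                            promoter_intercept = 0.1) {
  scenario <- match.arg(scenario)
  cfg <- config
  with_preserved_seed({
    set.seed(cfg$seed)
    genes <- sim_gene_table(cfg$n_genes)
    out <- list(config = cfg, scenario = scenario, genes = genes)

    if (scenario %in% c("null", "single-eqtl", "eqtl-mask")) {
      alpha <- switch(scenario, "null" = 0, "single-eqtl" = cfg$afc,
                      "eqtl-mask" = cfg$afc)
      variants <- bind_cols(
        tibble(variant_id = paste0(genes$gene_id, "_eqtl"),
               chrom = genes$chrom, pos = genes$tss + 1L - 500L,
               gene_id = genes$gene_id, maf = cfg$maf,
               effect = alpha, role = "eqtl"),
        sim_ref_alt(nrow(genes)))
      gt <- simulate_genotypes(variants, cfg$n_samples)
      ratios <- expected_hap_ratios(gt, variants)
      mats <- purrr::map(seq_len(cfg$n_tissues),
                         ~ simulate_hap_counts(ratios, cfg))
      out$variants <- variants
      out$genotypes <- gt
      out$matrices <- mats
      out$eqtl_list <- select(variants, "variant_id", "gene_id",
                              "chrom", "pos", "ref", "alt")
      out$truth <- list(effects = select(variants, "variant_id", "gene_id",
                                         "effect"),
                        ratios = ratios)
      if (scenario == "eqtl-mask") {
        n_listed <- round(listed_frac * nrow(genes))
        listed <- variants$gene_id %in% genes$gene_id[seq_len(n_listed)]
        out$eqtl_table <- variants[listed, ] |>
          select("variant_id", "gene_id") |>
          mutate(class = "top")
        out$truth$listed <- tibble(gene_id = variants$gene_id,
                                   listed = listed)
      }
    }

    if (scenario == "genotype-errors") {
      coding <- purrr::map(seq_len(cfg$n_coding_snps), function(k) {
        bind_cols(
          tibble(variant_id = paste0(genes$gene_id, "_cs", k),
                 chrom = genes$chrom,
                 pos = genes$start + 1L + 1000L * k,
                 gene_id = genes$gene_id, maf = cfg$maf,
                 effect = 0, role = "coding"),
          sim_ref_alt(nrow(genes)))
      }) |> bind_rows()
      gt <- simulate_genotypes(coding, cfg$n_samples)
      ratios <- expected_hap_ratios(gt, coding)
      snp <- simulate_snp_counts(gt, coding, ratios, cfg)
      out$variants <- coding
      out$genotypes <- gt
      out$snp_counts <- snp$records
      out$snp_truth <- snp$truth
      out$truth <- list(error_sites = filter(snp$truth,
                                             .data$injected_error))
    }

    if (scenario == "rare-promoter") {
      spec <- maf_bin_spec()
      per_gene <- purrr::map(seq_len(nrow(genes)), function(i) {
        g <- genes[i, ]
        nb <- length(promoter_bin_mafs)
        k <- promoter_n_per_bin
        bind_cols(
          tibble(variant_id = sprintf("%s_pr%02d", g$gene_id,
                                      seq_len(nb * k)),
                 chrom = g$chrom,
                 pos = g$tss + 1L - 100L * seq_len(nb * k),
                 gene_id = g$gene_id,
                 maf = rep(promoter_bin_mafs, each = k),
                 effect = 0, role = "promoter",
                 bin = rep(spec$bin, each = k)),
          sim_ref_alt(nb * k))
      }) |> bind_rows()
      gt <- simulate_genotypes(per_gene, cfg$n_samples)
      het <- gt |>
        filter(.data$h1 + .data$h2 == 1) |>
        inner_join(select(per_gene, "variant_id", "gene_id", "bin"),
                   by = "variant_id") |>
        count(.data$sample_id, .data$gene_id, .data$bin) |>
        tidyr::pivot_wider(names_from = "bin", values_from = "n",
                           values_fill = 0L)
      base <- tidyr::expand_grid(sample_id = unique(gt$sample_id),
                                 gene_id = genes$gene_id) |>
        left_join(het, by = c("sample_id", "gene_id"))
      for (b in spec$bin) {
        if (!b %in% names(base)) base[[b]] <- 0L
        base[[b]] <- ifelse(is.na(base[[b]]), 0L, base[[b]])
      }
      X <- as.matrix(base[spec$bin])
      base$y <- promoter_intercept +
        as.numeric(X %*% promoter_bin_effects) +
        rnorm(nrow(base), sd = promoter_sd)
      out$variants <- per_gene
      out$genotypes <- gt
      out$design <- select(base, "sample_id", "gene_id", "y",
                           all_of(spec$bin))
      out$truth <- list(bin_effects = setNames(promoter_bin_effects,
                                               spec$bin),
                        intercept = promoter_intercept,
                        sd = promoter_sd)
    }
    structure(out, class = "ae_sim")
  })
}

#' Write a simulated cohort to disk
#'
#' Emits the phased VCF, per-tissue haplotypic expression matrices, SNP-level
#' count table, gene annotation BED, regulatory-variant list and a JSON
#' ground-truth file into a directory.
#'
#' @param sim An `ae_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim$genotypes)) {
    write_phased_vcf(sim$genotypes, file.path(dir, "sim.vcf.gz"))
  }
  if (!is.null(sim$matrices)) {
    for (i in seq_along(sim$matrices)) {
      write_hap_matrix(sim$matrices[[i]],
                       file.path(dir, sprintf("matrix_tissue%d.gw_phased.txt.gz",
                                              i)))
    }
  }
  if (!is.null(sim$snp_counts)) {
    write_snp_counts(sim$snp_counts, file.path(dir, "snp_counts.tsv"))
  }
  readr::write_tsv(sim$genes |>
                     select("chrom", "start", "end", "gene_id", "gene_type",
                            "strand"),
                   file.path(dir, "genes.bed"), col_names = FALSE,
                   progress = FALSE)
  if (!is.null(sim$eqtl_list)) {
    write_variant_list(sim$eqtl_list, file.path(dir, "eqtls.tsv"))
  }
  if (!is.null(sim$design)) {
    readr::write_tsv(sim$design, file.path(dir, "promoter_design.tsv"),
                     progress = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- purrr::map(sim$truth, function(x) {
      if (inherits(x, "data.frame")) as.data.frame(x) else x
    })
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
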