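#' Assign SNP allele-count records to genes
#'
#' Each site is assigned to every gene whose body contains it; sites inside
#' two or more overlapping genes are duplicated, one row per gene, and
#' intergenic sites keep `gene_id = NA`.
#'
#' @param records SNP allele-count tibble with `chrom` and 1-based `pos`.
#' @param genes Gene annotation from [read_gene_bed()] / [gene_annotation()]
#'   (0-based half-open intervals).
#' @param gene_types Optional character vector restricting assignment to
#'   given `gene_type`s (e.g. `c("protein_coding", "lincRNA")`); `NULL`
#'   keeps all.
#' @return `records` with a `gene_id` column (possibly more rows).
#' @export
assign_genes <- function(records, genes, gene_types = NULL) {
  if (!is.null(gene_types)) {
    genes <- filter(genes, .data$gene_type %in% gene_types)
  }
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  gr_sites <- GenomicRanges::GRanges(
    records$chrom, IRanges::IRanges(start = records$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes)
  records$gene_id <- NULL
  assigned <- records[S4Vectors::queryHits(hits), , drop = FALSE]
  assigned$gene_id <- genes$gene_id[S4Vectors::subjectHits(hits)]
  unassigned <- records[setdiff(seq_len(nrow(records)),
                                unique(S4Vectors::queryHits(hits))), ,
                        drop = FALSE]
  if (nrow(unassigned) > 0) unassigned$gene_id <- NA_character_
  bind_rows(assigned, unassigned)
}

all_allele_pairs <- function() {
  alleles <- c("A", "C", "G", "T")
  expand.grid(ref = alleles, alt = alleles, stringsAsFactors = FALSE) |>
    filter(.data$ref != .data$alt) |>
    arrange(.data$ref, .data$alt) |>
    as_tibble()
}

#' Estimate expected null reference-read fractions per allele pair
#'
#' Reference mapping bias makes the expected reference-read fraction at a
#' truly balanced heterozygous site deviate from 0.5, in a way that depends
#' on the ref/alt allele combination. This estimates the null ratio `p0` for
#' each of the 12 ordered SNP allele pairs as the median reference-read
#' fraction across qualifying sites (coverage at least `min_coverage`,
#' not flagged for low mappability or simulated mapping bias). Pairs with
#' fewer than `min_sites` qualifying sites fall back to `p0 = 0.5`.
#'
#' @param records SNP allele-count tibble.
#' @param min_coverage Minimum `ref_count + alt_count` for a site to inform
#'   the estimate (default 8).
#' @param min_sites Minimum number of qualifying sites per allele pair before
#'   the data-driven estimate replaces the 0.5 fallback (default 200).
#' @return A tibble with columns `ref`, `alt`, `p0`, `n_sites` covering all
#'   12 ordered allele pairs.
#' @export
estimate_null_ratios <- function(records, min_coverage = 8, min_sites = 200) {
  pairs <- all_allele_pairs()
  if (nrow(records) == 0) {
    warn("no records supplied; all null ratios default to 0.5")
    return(mutate(pairs, p0 = 0.5, n_sites = 0L))
  }
  use <- records |>
    filter(.data$ref_count + .data$alt_count >= min_coverage)
  for (fl in c("flag_low_mappability", "flag_mapping_bias")) {
    if (fl %in% names(use)) use <- use[!use[[fl]], , drop = FALSE]
  }
  est <- use |>
    mutate(frac = .data$ref_count / (.data$ref_count + .data$alt_count)) |>
    group_by(.data$ref, .data$alt) |>
    summarise(p0_hat = median(.data$frac), n_sites = n(), .groups = "drop")
  pairs |>
    left_join(est, by = c("ref", "alt")) |>
    mutate(n_sites = ifelse(is.na(.data$n_sites), 0L, .data$n_sites),
           p0 = ifelse(.data$n_sites >= min_sites & !is.na(.data$p0_hat) &
                         .data$p0_hat > 0 & .data$p0_hat < 1,
                       .data$p0_hat, 0.5)) |>
    select("ref", "alt", "p0", "n_sites")
}

#' Binomial allelic-expression test against allele-pair null ratios
#'
#' Adds the expected null reference fraction (`null_ratio`), an exact
#' two-sided binomial p-value of the observed reference count against it,
#' and a Benjamini-Hochberg q-value computed independently within each
#' tissue. Only sites with coverage at least `min_coverage` are tested;
#' untested sites get `NA`.
#'
#' @param records SNP allele-count tibble (needs `ref`, `alt`, `ref_count`,
#'   `alt_count`; `tissue_id` if per-tissue correction is wanted).
#' @param null_ratios Null-ratio table from [estimate_null_ratios()], or
#'   `NULL` for a flat 0.5 null.
#' @param min_coverage Minimum coverage for testing (default 8).
#' @return `records` with `null_ratio`, `p_value` and `q_value` columns.
#' @export
add_ae_pvalues <- function(records, null_ratios = NULL, min_coverage = 8) {
  if (is.null(null_ratios)) {
    null_ratios <- mutate(all_allele_pairs(), p0 = 0.5, n_sites = 0L)
  }
  records <- records |>
    left_join(select(null_ratios, "ref", "alt", "p0"),
              by = c("ref", "alt")) |>
    mutate(null_ratio = ifelse(is.na(.data$p0), 0.5, .data$p0), p0 = NULL)
  total <- records$ref_count + records$alt_count
  tested <- total >= min_coverage & total >= 1
  records$p_value <- NA_real_
  records$p_value[tested] <- binom_test_two_sided(
    records$ref_count[tested], total[tested], records$null_ratio[tested])
  if (!"tissue_id" %in% names(records)) records$tissue_id <- "tissue1"
  records |>
    group_by(.data$tissue_id) |>
    mutate(q_value = {
      q <- rep(NA_real_, n())
      ok <- !is.na(.data$p_value)
      q[ok] <- p.adjust(.data$p_value[ok], method = "BH")
      q
    }) |>
    ungroup()
}

#' Flag sites in low-mappability regions
#'
#' @param records SNP allele-count tibble.
#' @param mappability_bed Tibble of low-mappability intervals with columns
#'   `chrom`, `start`, `end` (0-based half-open); need not be sorted.
#' @return `records` with a logical `flag_low_mappability` column. A site at
#'   1-based `pos` is flagged iff `start <= pos - 1 < end` for any interval.
#' @export
flag_low_mappability <- function(records, mappability_bed) {
  records$flag_low_mappability <- FALSE
  if (is.null(mappability_bed) || nrow(mappability_bed) == 0) return(records)
  bed <- arrange(mappability_bed, .data$chrom, .data$start)
  gr_bed <- GenomicRanges::GRanges(
    bed$chrom, IRanges::IRanges(start = bed$start + 1L, end = bed$end))
  gr_sites <- GenomicRanges::GRanges(
    records$chrom, IRanges::IRanges(start = records$pos, width = 1L))
  records$flag_low_mappability <-
    GenomicRanges::countOverlaps(gr_sites, gr_bed) > 0
  records
}

#' Flag sites on a mapping-bias blacklist
#'
#' Sites shown to be biased in upstream read simulations are consumed as a
#' blacklist of positions; this package does not simulate biased reads.
#'
#' @param records SNP allele-count tibble.
#' @param bias_sites Tibble with `chrom` and 1-based `pos` of blacklisted
#'   sites, or `NULL`.
#' @return `records` with a logical `flag_mapping_bias` column.
#' @export
flag_mapping_bias <- function(records, bias_sites) {
  records$flag_mapping_bias <- FALSE
  if (is.null(bias_sites) || nrow(bias_sites) == 0) return(records)
  key <- paste(bias_sites$chrom, bias_sites$pos)
  records$flag_mapping_bias <- paste(records$chrom, records$pos) %in% key
  records
}

#' Estimate the per-read sequencing noise rate
#'
#' The fraction of reads supporting neither the reference nor the alternate
#' allele, pooled over all sites: `sum(other) / sum(ref + alt + other)`.
#'
#' @param records SNP allele-count tibble with `other_count`.
#' @return Scalar noise rate estimate.
#' @export
estimate_noise_rate <- function(records) {
  tot <- sum(records$ref_count) + sum(records$alt_count) +
    sum(records$other_count)
  if (tot == 0) abort("cannot estimate noise rate from zero reads")
  sum(records$other_count) / tot
}

#' Flag possible genotyping errors (genotype warning)
#'
#' A nominally heterozygous site whose minor-allele read count is no larger
#' than sequencing noise alone would produce is likely a mis-genotyped
#' homozygous site. Per site, a one-sided binomial test of
#' `P(X >= min(ref, alt))` under `X ~ Binomial(ref + alt, epsilon)` asks
#' whether the minor allele is supported above noise; sites whose test is
#' *not* significant after Benjamini-Hochberg correction at `fdr` across all
#' tested sites receive the warning. The warning cannot distinguish strong
#' mono-allelic expression from a genotyping error, so it should not be used
#' when mono-allelic expression is the phenomenon under study.
#'
#' @param records SNP allele-count tibble.
#' @param epsilon Per-read noise probability in (0, 0.5); if `NULL`,
#'   estimated from `other_count` via [estimate_noise_rate()].
#' @param fdr BH threshold for calling minor-allele support significant
#'   (default 0.01).
#' @return `records` with `flag_genotype_warning` (logical) and
#'   `noise_p_value` columns.
#' @export
genotype_warning <- function(records, epsilon = 0.005, fdr = 0.01) {
  if (is.null(epsilon)) {
    if (!"other_count" %in% names(records)) {
      abort("epsilon not given and other_count absent; cannot estimate noise")
    }
    epsilon <- estimate_noise_rate(records)
    if (epsilon <= 0) abort("estimated noise rate is zero; supply epsilon")
  }
  if (epsilon <= 0 || epsilon >= 0.5) {
    abort("epsilon must lie in (0, 0.5)")
  }
  n <- records$ref_count + records$alt_count
  minor <- pmin(records$ref_count, records$alt_count)
  tested <- n >= 1
  p <- rep(NA_real_, nrow(records))
  p[tested] <- binom_tail_upper(minor[tested], n[tested], epsilon)
  q <- rep(NA_real_, nrow(records))
  q[tested] <- p.adjust(p[tested], method = "BH")
  records$noise_p_value <- p
  records$flag_genotype_warning <- tested & !(q < fdr)
  records
}

#' Annotate a SNP-level allele-count table
#'
#' Full SNP-level annotation pipeline: gene assignment, low-mappability and
#' mapping-bias flags, allele-pair null-ratio estimation (from the unflagged
#' high-coverage sites themselves unless a table is supplied), exact binomial
#' allelic-imbalance p-values against the null ratios with per-tissue BH
#' correction, and the genotype warning.
#'
#' @inheritParams assign_genes
#' @inheritParams add_ae_pvalues
#' @inheritParams genotype_warning
#' @param mappability_bed Optional low-mappability intervals (see
#'   [flag_low_mappability()]).
#' @param bias_sites Optional mapping-bias blacklist (see
#'   [flag_mapping_bias()]).
#' @param min_sites Minimum sites per allele pair for null-ratio estimation.
#' @return Annotated tibble of SNP AE records.
#' @export
annotate_snp_ae <- function(records, genes = NULL, mappability_bed = NULL,
                            bias_sites = NULL, null_ratios = NULL,
                            min_coverage = 8, min_sites = 200,
                            epsilon = 0.005, fdr = 0.01,
                            gene_types = NULL) {
  if (!is.null(genes)) {
    records <- assign_genes(records, genes, gene_types = gene_types)
  }
  records <- flag_low_mappability(records, mappability_bed)
  records <- flag_mapping_bias(records, bias_sites)
  if (is.null(null_ratios)) {
    null_ratios <- estimate_null_ratios(records, min_coverage = min_coverage,
                                        min_sites = min_sites)
  }
  records <- add_ae_pvalues(records, null_ratios,
                            min_coverage = min_coverage)
  genotype_warning(records, epsilon = epsilon, fdr = fdr)
}
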