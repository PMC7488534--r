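#' Per-sample allelic fold change from haplotypic counts
#'
#' The allelic fold change (aFC) of a regulatory variant in one sample is
#' `log2((alt_hap_count + 1) / (ref_hap_count + 1))`: the log2 expression
#' ratio of the haplotype carrying the variant's alternate allele over the
#' reference-allele haplotype, with +1 pseudocounts. Balanced counts (and
#' the degenerate `(0, 0)` cell) give 0.
#'
#' @param alt_hap_count Reads on the alternate-allele haplotype.
#' @param ref_hap_count Reads on the reference-allele haplotype.
#' @return Numeric vector of log2 allelic fold changes.
#' @export
sample_afc <- function(alt_hap_count, ref_hap_count) {
  stopifnot(all(alt_hap_count >= 0), all(ref_hap_count >= 0))
  log2((alt_hap_count + 1) / (ref_hap_count + 1))
}

# Clopper-Pearson interval on the alt-haplotype read fraction, mapped through
# the aFC formula at the observed total coverage.
afc_ci_from_counts <- function(alt, ref, level = 0.95) {
  n <- alt + ref
  a <- (1 - level) / 2
  lo_p <- ifelse(alt == 0, 0, qbeta(a, alt, n - alt + 1))
  hi_p <- ifelse(alt == n, 1, qbeta(1 - a, alt + 1, n - alt))
  tibble(afc_lo = log2((n * lo_p + 1) / (n * (1 - lo_p) + 1)),
         afc_hi = log2((n * hi_p + 1) / (n * (1 - hi_p) + 1)))
}

#' Orient haplotypic counts by a phased genotype
#'
#' For a sample heterozygous at a regulatory variant, assigns the gene's
#' haplotype A/B counts to the variant's alternate and reference alleles
#' using the phased genotype. The orientation contract is that haplotype 1
#' of the phased VCF corresponds to HAP_A of a genome-wide-phased matrix:
#' if `h1 = 1` (alt on haplotype 1) the alt-haplotype count is `hapA`,
#' otherwise `hapB`. Homozygous samples have no meaningful orientation and
#' keep `(hapA, hapB)` as-is.
#'
#' @param h1,h2 Phased haplotype alleles (0/1) per sample.
#' @param hapA,hapB Haplotypic read counts per sample.
#' @param phased Logical; was the genotype phased? Unphased heterozygotes
#'   cannot be oriented and are classed `"unphased"`.
#' @return Tibble with `genotype_class` (`het`, `hom_ref`, `hom_alt`,
#'   `unphased`, `missing`), `alt_hap` and `ref_hap` (het rows only; `NA`
#'   otherwise).
#' @export
orient_haplotype_counts <- function(h1, h2, hapA, hapB, phased = TRUE) {
  m <- length(h1)
  phased <- rep_len(phased, m)
  cls <- case_when(
    is.na(h1) | is.na(h2) | is.na(hapA) | is.na(hapB) ~ "missing",
    h1 + h2 == 1 & !phased ~ "unphased",
    h1 + h2 == 1 ~ "het",
    h1 == 1 ~ "hom_alt",
    TRUE ~ "hom_ref"
  )
  het <- cls == "het"
  alt_hap <- ifelse(het, ifelse(h1 == 1, hapA, hapB), NA_integer_)
  ref_hap <- ifelse(het, ifelse(h1 == 1, hapB, hapA), NA_integer_)
  tibble(genotype_class = cls, alt_hap = alt_hap, ref_hap = ref_hap)
}

# Seeded nonparametric bootstrap percentile CI of the median; values are
# sorted first so the interval is invariant to input order.
boot_median_ci <- function(values, boot_B = 1000, level = 0.95,
                           seed = NULL) {
  values <- sort(values)
  n <- length(values)
  if (n < 2) return(c(NA_real_, NA_real_))
  if (!is.null(seed)) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
  }
  idx <- matrix(sample.int(n, n * boot_B, replace = TRUE), nrow = boot_B)
  meds <- matrixStats_rowMedians(matrix(values[idx], nrow = boot_B))
  a <- (1 - level) / 2
  unname(quantile(meds, c(a, 1 - a), type = 7))
}

# row medians without extra dependencies
matrixStats_rowMedians <- function(m) apply(m, 1, median)

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Estimate regulatory-variant effect sizes from phased haplotypic counts
#'
#' For each regulatory variant (e.g. an eQTL) paired with a gene, phases the
#' variant with the gene's haplotype-level expression in every individual,
#' computes the per-sample allelic fold change (aFC, see [sample_afc()]) with
#' an exact binomial-proportion confidence interval, and summarizes across
#' individuals: the median aFC over heterozygotes (the effect-size estimate)
#' with a seeded bootstrap percentile CI, the median absolute aFC over
#' homozygotes, and a one-sided rank-sum (Mann-Whitney) test of whether
#' absolute aFC is higher in heterozygotes than homozygotes — true
#' regulatory variants are expected to show the excess.
#'
#' @param variants Tibble with columns `variant_id` and `gene_id` (e.g. from
#'   [read_variant_list()]).
#' @param gt A `phased_gt` genotype table containing the variants.
#' @param mat A genome-wide-phased `hap_matrix`; anything else is a hard
#'   error because haplotype A/B labels would be arbitrary.
#' @param min_coverage Per-sample minimum haplotypic coverage (hapA + hapB)
#'   for a cell to enter the statistics (default 8).
#' @param ci_level Confidence level for all intervals (default 0.95).
#' @param boot_B Bootstrap replicates for the median CI (default 1000).
#' @param seed Integer seed making the bootstrap deterministic.
#' @return An object of class `cis_var_result`: list with `summary` (one row
#'   per variant-gene pair), `samples` (all underlying per-sample data) and
#'   `skipped` (variants that could not be scored, with reasons). Use
#'   [tidy()] to extract the summary tibble.
#' @export
run_cis_var <- function(variants, gt, mat, min_coverage = 8,
                        ci_level = 0.95, boot_B = 1000, seed = 1L) {
  if (!is_gw_phased(mat)) {
    abort(paste0("haplotypic expression matrix is not genome-wide phased; ",
                 "haplotype A/B labels cannot be joined to the VCF"))
  }
  variants <- as_tibble(variants)
  if (!all(c("variant_id", "gene_id") %in% names(variants))) {
    abort("variants need variant_id and gene_id columns")
  }
  dup <- duplicated(variants[c("variant_id", "gene_id")])
  if (any(dup)) {
    warn(paste0(sum(dup), " duplicated variant-gene pair(s) removed"))
    variants <- variants[!dup, , drop = FALSE]
  }

  known_variants <- unique(gt$variant_id)
  known_genes <- unique(mat$gene_id)
  skipped <- bind_rows(
    variants |>
      filter(!.data$variant_id %in% known_variants) |>
      mutate(reason = "variant_not_in_vcf"),
    variants |>
      filter(.data$variant_id %in% known_variants,
             !.data$gene_id %in% known_genes) |>
      mutate(reason = "gene_not_in_matrix")
  ) |> select("variant_id", "gene_id", "reason")
  usable <- variants |>
    filter(.data$variant_id %in% known_variants,
           .data$gene_id %in% known_genes) |>
    arrange(.data$variant_id, .data$gene_id)

  per_sample_all <- list()
  summaries <- vector("list", nrow(usable))
  for (i in seq_len(nrow(usable))) {
    vid <- usable$variant_id[i]
    gid <- usable$gene_id[i]
    cells <- gt |>
      filter(.data$variant_id == vid) |>
      left_join(filter(as_tibble(mat), .data$gene_id == gid),
                by = "sample_id") |>
      arrange(.data$sample_id)
    ori <- orient_haplotype_counts(cells$h1, cells$h2, cells$hapA,
                                   cells$hapB, cells$phased)
    rows <- bind_cols(
      tibble(variant_id = vid, gene_id = gid, sample_id = cells$sample_id,
             hapA = cells$hapA, hapB = cells$hapB), ori) |>
      mutate(coverage = .data$hapA + .data$hapB,
             pass = !is.na(.data$coverage) &
               .data$coverage >= min_coverage &
               .data$genotype_class %in% c("het", "hom_ref", "hom_alt"))
    het <- rows$pass & rows$genotype_class == "het"
    hom <- rows$pass & rows$genotype_class %in% c("hom_ref", "hom_alt")
    rows$afc <- NA_real_
    rows$afc_unoriented <- NA_real_
    rows$afc[het] <- sample_afc(rows$alt_hap[het], rows$ref_hap[het])
    # homozygotes: A/B orientation is arbitrary, so the afc field carries the
    # absolute value; the signed unoriented value is kept alongside
    rows$afc_unoriented[hom] <-
      log2((rows$hapA[hom] + 1) / (rows$hapB[hom] + 1))
    rows$afc[hom] <- abs(rows$afc_unoriented[hom])
    rows$abs_afc <- abs(rows$afc)
    ci <- tibble(afc_lo = rep(NA_real_, nrow(rows)), afc_hi = NA_real_)
    if (any(het)) {
      ci[het, ] <- afc_ci_from_counts(rows$alt_hap[het], rows$ref_hap[het],
                                      level = ci_level)
    }
    rows <- bind_cols(rows, ci)
    per_sample_all[[i]] <- rows

    het_afc <- rows$afc[het]
    hom_abs <- rows$abs_afc[hom]
    med <- if (length(het_afc) > 0) median(het_afc) else NA_real_
    med_ci <- boot_median_ci(het_afc, boot_B = boot_B, level = ci_level,
                             seed = if (is.null(seed)) NULL else seed + i)
    rp <- if (length(het_afc) > 0 && length(hom_abs) > 0) {
      suppressWarnings(
        wilcox.test(abs(het_afc), hom_abs, alternative = "greater")$p.value)
    } else NA_real_
    summaries[[i]] <- tibble(
      variant_id = vid, gene_id = gid,
      n_het = sum(het), n_hom = sum(hom),
      median_afc = med, median_afc_lo = med_ci[1], median_afc_hi = med_ci[2],
      median_abs_afc_hom = if (length(hom_abs) > 0) median(hom_abs)
                           else NA_real_,
      ranksum_p = rp)
  }

  structure(
    list(summary = bind_rows(summaries),
         samples = bind_rows(per_sample_all),
         skipped = skipped,
         params = list(min_coverage = min_coverage, ci_level = ci_level,
                       boot_B = boot_B, seed = seed)),
    class = "cis_var_result")
}

#' @rdname run_cis_var
#' @param variant_id,gene_id Single variant/gene pair to summarize.
#' @export
variant_afc_summary <- function(variant_id, gene_id, gt, mat,
                                min_coverage = 8, ci_level = 0.95,
                                boot_B = 1000, seed = 1L) {
  run_cis_var(tibble(variant_id = variant_id, gene_id = gene_id),
              gt, mat, min_coverage = min_coverage, ci_level = ci_level,
              boot_B = boot_B, seed = seed)
}

#' @export
print.cis_var_result <- function(x, ...) {
  cat("cis-regulatory variant aFC estimates\n")
  cat(" variants scored:", nrow(x$summary),
      " skipped:", nrow(x$skipped), "\n")
  print(x$summary, ...)
  invisible(x)
}

#' Tidy a `cis_var_result`
#'
#' @param x A `cis_var_result` from [run_cis_var()].
#' @param type `"summary"` for the per-variant effect sizes, `"samples"` for
#'   the underlying per-sample haplotypic counts and aFCs, `"skipped"` for
#'   unscored variants.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cis_var_result <- function(x, type = c("summary", "samples", "skipped"),
                                ...) {
  type <- match.arg(type)
  x[[type]]
}

#' @rdname tidy.cis_var_result
#' @export
glance.cis_var_result <- function(x, ...) {
  tibble(n_variants = nrow(x$summary),
         n_skipped = nrow(x$skipped),
         median_n_het = median(x$summary$n_het),
         boot_B = x$params$boot_B,
         ci_level = x$params$ci_level)
}
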