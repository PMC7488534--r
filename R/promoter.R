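#' Minor-allele-frequency bin specification
#'
#' The five MAF bins used to stratify promoter-proximal heterozygous
#' variants, ordered common to rare: 0.50-0.10, 0.10-0.05, 0.05-0.01,
#' 0.01-0.005, 0.005-0. A variant falls in the bin with
#' `lower <= MAF < upper`; the top bin is closed above because a minor
#' allele frequency cannot exceed 0.5.
#'
#' @return Tibble with `bin` (label), `lower`, `upper`.
#' @export
maf_bin_spec <- function() {
  tibble(bin = c("bin_0.50_0.10", "bin_0.10_0.05", "bin_0.05_0.01",
                 "bin_0.01_0.005", "bin_0.005_0"),
         lower = c(0.10, 0.05, 0.01, 0.005, 0),
         upper = c(0.50, 0.10, 0.05, 0.01, 0.005))
}

#' Assign minor allele frequencies to MAF bins
#'
#' @param maf Numeric vector of minor allele frequencies in (0, 0.5].
#' @param spec Bin specification, defaults to [maf_bin_spec()].
#' @return Integer vector of bin indices into `spec` (1 = commonest bin).
#' @export
assign_maf_bin <- function(maf, spec = maf_bin_spec()) {
  if (any(maf > 0.5)) abort("MAF > 0.5 is not a minor allele frequency")
  if (any(maf <= 0)) abort("MAF must be positive (monomorphic sites excluded)")
  idx <- rep(NA_integer_, length(maf))
  for (i in seq_len(nrow(spec))) {
    in_bin <- maf >= spec$lower[i] &
      (maf < spec$upper[i] | (spec$upper[i] == 0.5 & maf <= 0.5))
    idx[in_bin & is.na(idx)] <- i
  }
  idx
}

#' Within-cohort allele frequencies from phased genotypes
#'
#' @param gt A `phased_gt` table.
#' @return Tibble `variant_id`, `alt_freq`, `maf`.
#' @export
compute_allele_freqs <- function(gt) {
  gt |>
    group_by(.data$variant_id) |>
    summarise(alt_freq = mean(c(.data$h1, .data$h2), na.rm = TRUE),
              .groups = "drop") |>
    mutate(maf = pmin(.data$alt_freq, 1 - .data$alt_freq))
}

#' Build the promoter-variant design table
#'
#' One row per individual by gene with haplotype-level AE data in at least
#' one tissue. The response `y` is the median across tissues of the absolute
#' allelic fold change `|log2((hapA + 1) / (hapB + 1))|` from
#' coverage-passing cells; the predictors are the number of heterozygous
#' variants carried by the individual in the gene's promoter-proximal window
#' (10 kb upstream of the TSS, strand-aware), one count per MAF bin. Allele
#' frequencies are computed within the analyzed cohort itself unless
#' supplied (cohorts with population structure yield unreliable frequencies
#' for population-specific variants, so supply externally stratified cohorts
#' with care). Individuals with no heterozygous promoter variants are
#' retained with all-zero counts.
#'
#' @param mats A `hap_matrix` or list of them (one per tissue).
#' @param gt A `phased_gt` table including the promoter-region variants.
#' @param genes Gene annotation from [gene_annotation()].
#' @param window Window size upstream of the TSS in bp (default 10000).
#' @param min_coverage Minimum cell coverage entering `y` (default 8).
#' @param strand_aware If `FALSE`, the window is taken left of the TSS for
#'   every gene regardless of strand.
#' @param allele_freqs Optional tibble `variant_id`, `maf` overriding
#'   within-cohort frequencies.
#' @param gene_types Gene types kept (default protein-coding and lincRNA).
#' @param spec MAF bin specification.
#' @return Tibble `sample_id`, `gene_id`, `y`, plus one count column per bin.
#' @export
build_promoter_design <- function(mats, gt, genes, window = 10000,
                                  min_coverage = 8, strand_aware = TRUE,
                                  allele_freqs = NULL,
                                  gene_types = c("protein_coding", "lincRNA"),
                                  spec = maf_bin_spec()) {
  if (inherits(mats, "hap_matrix")) mats <- list(mats)
  genes <- filter(genes, .data$gene_type %in% gene_types)

  # response: median absolute aFC across tissues
  cells <- purrr::imap(mats, function(m, i) {
    filter_hap_matrix(m, min_coverage) |>
      as_tibble() |>
      mutate(tissue = i)
  }) |> bind_rows()
  y_tbl <- cells |>
    mutate(abs_afc = abs(log2((.data$hapA + 1) / (.data$hapB + 1)))) |>
    group_by(.data$gene_id, .data$sample_id) |>
    summarise(y = median(.data$abs_afc), .groups = "drop")
  no_tss <- setdiff(unique(y_tbl$gene_id), genes$gene_id)
  if (length(no_tss) > 0) {
    message(length(no_tss), " gene(s) without annotation/TSS skipped")
    y_tbl <- filter(y_tbl, .data$gene_id %in% genes$gene_id)
  }

  # promoter windows, 1-based inclusive, strand-aware upstream of the TSS
  tss1 <- genes$tss + 1L
  win_start <- ifelse(!strand_aware | genes$strand == "+",
                      tss1 - window + 1L, tss1)
  win_end <- ifelse(!strand_aware | genes$strand == "+",
                    tss1, tss1 + window - 1L)
  gr_win <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = pmax(1L, win_start), end = win_end))

  vars <- distinct(gt, .data$variant_id, .data$chrom, .data$pos)
  gr_var <- GenomicRanges::GRanges(
    vars$chrom, IRanges::IRanges(start = vars$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr_var, gr_win)
  var_gene <- tibble(variant_id = vars$variant_id[S4Vectors::queryHits(hits)],
                     gene_id = genes$gene_id[S4Vectors::subjectHits(hits)])

  freqs <- allele_freqs %||% compute_allele_freqs(gt)
  var_gene <- var_gene |>
    left_join(select(freqs, "variant_id", "maf"), by = "variant_id") |>
    filter(!is.na(.data$maf) & .data$maf > 0)
  var_gene$bin <- spec$bin[assign_maf_bin(var_gene$maf, spec)]

  het_counts <- gt |>
    filter(!is.na(.data$h1) & !is.na(.data$h2) &
             .data$h1 + .data$h2 == 1) |>
    inner_join(var_gene, by = "variant_id",
               relationship = "many-to-many") |>
    count(.data$sample_id, .data$gene_id, .data$bin) |>
    tidyr::pivot_wider(names_from = "bin", values_from = "n",
                       values_fill = 0L)
  for (b in spec$bin) {
    if (!b %in% names(het_counts)) het_counts[[b]] <- 0L
  }

  y_tbl |>
    left_join(het_counts, by = c("sample_id", "gene_id")) |>
    mutate(across(all_of(spec$bin), ~ ifelse(is.na(.x), 0L, .x))) |>
    select("sample_id", "gene_id", "y", all_of(spec$bin))
}

#' Fit the promoter MAF-bin linear model
#'
#' Ordinary least squares of absolute allelic imbalance on the per-bin
#' heterozygous promoter-variant counts, with an intercept by default. The
#' per-coefficient 95% confidence intervals come from the standard OLS
#' covariance and Student-t quantiles. A coefficient measures the expected
#' increase in absolute aFC per additional heterozygous promoter variant of
#' that frequency class, so rare-variant classes with larger coefficients
#' indicate stronger per-variant regulatory effects.
#'
#' @param design Design tibble from [build_promoter_design()] (columns `y`
#'   and the `bin_*` counts).
#' @param intercept Include an intercept (default `TRUE`)?
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `promoter_fit` wrapping the `lm` fit; use
#'   [tidy()] / [glance()] / [autoplot()].
#' @export
fit_promoter_model <- function(design, intercept = TRUE, conf_level = 0.95) {
  bin_cols <- grep("^bin_", names(design), value = TRUE)
  if (length(bin_cols) == 0) abort("design has no bin_* predictor columns")
  if (!"y" %in% names(design)) abort("design has no response column y")
  if (nrow(design) < length(bin_cols) + 2) {
    abort("too few rows to fit the promoter model")
  }
  X <- as.matrix(design[bin_cols])
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  fml <- if (intercept) y ~ . else y ~ . + 0
  fit <- lm(fml, data = design[c("y", bin_cols)])
  ci <- confint(fit, level = conf_level)
  terms <- tibble(term = names(coef(fit)),
                  estimate = unname(coef(fit)),
                  std_error = unname(sqrt(diag(stats::vcov(fit)))),
                  conf_low = ci[, 1],
                  conf_high = ci[, 2])
  structure(list(fit = fit, terms = terms, conf_level = conf_level,
                 n_rows = nrow(design), bins = bin_cols),
            class = "promoter_fit")
}

#' @export
print.promoter_fit <- function(x, ...) {
  cat("promoter MAF-bin linear model (", x$n_rows, " individual x gene rows)\n",
      sep = "")
  print(x$terms, ...)
  invisible(x)
}

#' Tidy / glance methods for `promoter_fit`
#'
#' @param x A `promoter_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per model term with estimate, standard error
#'   and confidence bounds. `glance()`: one-row model summary.
#' @export
tidy.promoter_fit <- function(x, ...) x$terms

#' @rdname tidy.promoter_fit
#' @export
glance.promoter_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r_squared = s$r.squared, sigma = s$sigma,
         nobs = x$n_rows, df_residual = x$fit$df.residual)
}
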