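#' Plot per-sample aFC by genotype class for a scored variant
#'
#' Shows the per-sample absolute allelic fold change split by genotype class
#' for one variant-gene pair — the visual counterpart of the rank-sum test:
#' a true regulatory variant shows higher absolute aFC in heterozygotes.
#'
#' @param object A `cis_var_result`.
#' @param variant Variant id to plot (default: the first scored variant).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cis_var_result <- function(object, variant = NULL, ...) {
  variant <- variant %||% object$summary$variant_id[1]
  df <- object$samples |>
    filter(.data$variant_id == variant, .data$pass,
           .data$genotype_class %in% c("het", "hom_ref", "hom_alt")) |>
    mutate(class = ifelse(.data$genotype_class == "het", "het", "hom"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$abs_afc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "|aFC| (log2)",
                  title = paste0(variant, ": allelic fold change by genotype"))
}

#' Plot promoter MAF-bin effect estimates
#'
#' Coefficient estimates and confidence intervals for the per-bin effect of
#' heterozygous promoter-proximal variants on absolute allelic imbalance,
#' ordered common to rare.
#'
#' @param object A `promoter_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.promoter_fit <- function(object, ...) {
  df <- object$terms |>
    filter(.data$term %in% object$bins) |>
    mutate(term = factor(.data$term, levels = object$bins,
                         labels = sub("^bin_", "", object$bins)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "MAF bin", y = "effect on |aFC| per het variant")
}

#' Plot imbalanced-gene counts against the sample threshold
#'
#' Counts of genes with significant allelic imbalance in at least n samples,
#' with and (when available) without eQTL-heterozygote masking.
#'
#' @param counts Output of [count_imbalanced_genes()].
#' @param percent Plot percentages instead of counts.
#' @return A ggplot object.
#' @export
plot_imbalance_counts <- function(counts, percent = FALSE) {
  value_cols <- if (percent) c("pct_genes", "pct_genes_masked")
                else c("n_genes", "n_genes_masked")
  value_cols <- intersect(value_cols, names(counts))
  df <- counts |>
    tidyr::pivot_longer(all_of(value_cols), names_to = "set",
                        values_to = "value") |>
    mutate(set = ifelse(grepl("masked", .data$set),
                        "eQTL hets excluded", "all samples"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$min_samples, y = .data$value,
                                   color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "minimum significant samples per gene",
                  y = if (percent) "% of AE genes" else "genes",
                  color = NULL)
}
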