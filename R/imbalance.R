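#' Test gene-by-sample allelic imbalance
#'
#' Per gene-sample cell, an exact two-sided binomial test of the haplotype A
#' count against an expected 50/50 split (the haplotype-level null is 0.5:
#' read-level reference bias affects both haplotypes' sites and washes out in
#' aggregated counts). Multiple testing is corrected with Benjamini-Hochberg.
#' Two correction universes are offered because "gene-level FDR" can be read
#' two ways:
#' \describe{
#'   \item{`"cell"` (default)}{BH across all tested gene-by-sample cells;
#'     a cell is significant iff its q-value is below `fdr`.}
#'   \item{`"gene"`}{a per-gene Bonferroni-adjusted minimum p across the
#'     gene's cells is BH-corrected across genes; all cells of a significant
#'     gene whose nominal p passes the gene's Bonferroni threshold are
#'     marked significant.}
#' }
#'
#' @param mat A `hap_matrix`, already coverage-filtered (see
#'   [filter_hap_matrix()]).
#' @param fdr FDR threshold (default 0.05).
#' @param level `"cell"` or `"gene"` correction universe.
#' @return Tibble with one row per tested cell: `gene_id`, `sample_id`,
#'   `hapA`, `hapB`, `p_value`, `q_value`, `significant`.
#' @export
test_imbalance <- function(mat, fdr = 0.05, level = c("cell", "gene")) {
  level <- match.arg(level)
  df <- as_tibble(mat)
  if (nrow(df) == 0) {
    return(tibble(gene_id = character(), sample_id = character(),
                  hapA = integer(), hapB = integer(), p_value = numeric(),
                  q_value = numeric(), significant = logical()))
  }
  df$p_value <- binom_test_two_sided(df$hapA, df$hapA + df$hapB, 0.5)
  if (level == "cell") {
    df$q_value <- p.adjust(df$p_value, method = "BH")
    df$significant <- df$q_value < fdr
  } else {
    gene_p <- df |>
      group_by(.data$gene_id) |>
      summarise(m = n(), p_min = min(.data$p_value), .groups = "drop") |>
      mutate(p_gene = pmin(1, .data$p_min * .data$m),
             q_gene = p.adjust(.data$p_gene, method = "BH"))
    df <- df |>
      left_join(select(gene_p, "gene_id", "m", "q_gene"), by = "gene_id") |>
      mutate(q_value = .data$q_gene,
             significant = .data$q_gene < fdr &
               .data$p_value * .data$m <= fdr) |>
      select(-"m", -"q_gene")
  }
  df
}

#' Mark samples heterozygous for a gene's listed eQTLs
#'
#' Builds the (gene, sample) mask used to ask how much allelic imbalance
#' remains once known eQTL effects are removed: a cell is masked iff the
#' sample is heterozygous for at least one listed eQTL of the gene (top or
#' independent, any class). Listed eQTLs absent from the genotypes raise a
#' warning and never mask.
#'
#' @param eqtls Tibble with `gene_id` and `variant_id` (optionally `class`).
#' @param gt A `phased_gt` genotype table.
#' @return Tibble `gene_id`, `sample_id`, `masked` covering every sample for
#'   every listed gene.
#' @export
build_eqtl_het_mask <- function(eqtls, gt) {
  absent <- setdiff(unique(eqtls$variant_id), unique(gt$variant_id))
  if (length(absent) > 0) {
    warn(paste0(length(absent),
                " listed eQTL(s) absent from genotypes; treated as never",
                " heterozygous"))
  }
  het_tbl <- gt |>
    inner_join(select(eqtls, "gene_id", "variant_id"), by = "variant_id",
               relationship = "many-to-many") |>
    mutate(het = !is.na(.data$h1) & !is.na(.data$h2) &
             .data$h1 + .data$h2 == 1) |>
    group_by(.data$gene_id, .data$sample_id) |>
    summarise(masked = any(.data$het), .groups = "drop")
  tidyr::expand_grid(gene_id = unique(eqtls$gene_id),
                     sample_id = unique(gt$sample_id)) |>
    left_join(het_tbl, by = c("gene_id", "sample_id")) |>
    mutate(masked = !is.na(.data$masked) & .data$masked)
}

#' Remove eQTL-heterozygote cells from a haplotypic matrix
#'
#' Drops every gene-sample cell whose sample is heterozygous for a listed
#' eQTL of that gene, so imbalance can be re-tested on the remaining data.
#'
#' @param mat A `hap_matrix`.
#' @param mask Mask from [build_eqtl_het_mask()].
#' @return Masked `hap_matrix`.
#' @export
mask_hap_matrix <- function(mat, mask) {
  masked_cells <- filter(mask, .data$masked)
  out <- anti_join(as_tibble(mat), masked_cells,
                   by = c("gene_id", "sample_id"))
  hap_matrix(out, gw_phased = is_gw_phased(mat))
}

#' Count genes with significant imbalance in at least n samples
#'
#' For each threshold `n` in `min_samples`, counts genes whose number of
#' significantly imbalanced samples is at least `n` — once over all samples
#' and, when a mask is supplied, once after removing cells whose sample is
#' heterozygous for a listed eQTL of the gene. Also reports the counts as a
#' percentage of all genes with AE data.
#'
#' @param results Cell-level results from [test_imbalance()].
#' @param mask Optional mask from [build_eqtl_het_mask()].
#' @param min_samples Integer grid of sample thresholds (default 1:10).
#' @return Tibble with `min_samples`, `n_genes`, `pct_genes` and, when a mask
#'   is given, `n_genes_masked`, `pct_genes_masked`.
#' @export
count_imbalanced_genes <- function(results, mask = NULL,
                                   min_samples = 1:10) {
  n_ae_genes <- dplyr::n_distinct(results$gene_id)
  count_at <- function(cells) {
    sig <- cells |>
      group_by(.data$gene_id) |>
      summarise(n_sig = sum(.data$significant), .groups = "drop")
    vapply(min_samples, function(n) sum(sig$n_sig >= n), integer(1))
  }
  out <- tibble(min_samples = as.integer(min_samples),
                n_genes = count_at(results),
                pct_genes = 100 * count_at(results) / max(1, n_ae_genes))
  if (!is.null(mask)) {
    kept <- anti_join(results, filter(mask, .data$masked),
                      by = c("gene_id", "sample_id"))
    out$n_genes_masked <- count_at(kept)
    out$pct_genes_masked <- 100 * out$n_genes_masked / max(1, n_ae_genes)
  }
  out
}
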