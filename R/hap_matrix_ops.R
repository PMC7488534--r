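#' Aggregate per-sample haplotypic counts into a population matrix
#'
#' Combines per-sample gene-level haplotypic count tables into one matrix
#' with a row per gene and a column per sample (stored long, see
#' [hap_matrix()]). The gene universe is the union across samples; a gene
#' absent from a sample is a missing cell. When `require_gw_phased` is
#' `TRUE`, gene-sample entries whose haplotype assignment could not be
#' phased genome-wide are dropped (become missing) and the resulting matrix
#' is marked genome-wide phased; otherwise all counts are kept but the A/B
#' labels are arbitrary per gene and the matrix refuses downstream joins to
#' genotypes.
#'
#' @param per_sample A list of tibbles, one per sample, each with columns
#'   `gene_id`, `hapA`, `hapB` and logical `gw_phased`, and either a
#'   `sample_id` column or a named list.
#' @param require_gw_phased Keep only genome-wide-phased entries?
#' @return A `hap_matrix`.
#' @export
build_hap_matrix <- function(per_sample, require_gw_phased = TRUE) {
  if (!is.null(names(per_sample))) {
    per_sample <- purrr::imap(per_sample, function(df, nm) {
      if (!"sample_id" %in% names(df)) df$sample_id <- nm
      df
    })
  }
  combined <- bind_rows(per_sample)
  if (!"sample_id" %in% names(combined)) {
    abort("per-sample tables need a sample_id column or a named list")
  }
  if (!"gw_phased" %in% names(combined)) combined$gw_phased <- TRUE
  ids <- purrr::map_chr(per_sample, ~ unique(.x$sample_id)[1])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (require_gw_phased) {
    combined <- filter(combined, .data$gw_phased)
  }
  hap_matrix(select(combined, "gene_id", "sample_id", "hapA", "hapB"),
             gw_phased = require_gw_phased)
}

#' Filter a haplotypic expression matrix by coverage
#'
#' Cells with fewer than `min_coverage` total reads (hapA + hapB) become
#' missing; genes left with no cells are dropped. Idempotent.
#'
#' @param mat A `hap_matrix`.
#' @param min_coverage Minimum total reads per cell (default 8; the boundary
#'   is inclusive, a cell with exactly `min_coverage` reads is kept).
#' @return Filtered `hap_matrix`.
#' @export
filter_hap_matrix <- function(mat, min_coverage = 8) {
  out <- filter(as_tibble(mat), .data$hapA + .data$hapB >= min_coverage)
  hap_matrix(out, gw_phased = is_gw_phased(mat))
}

#' Summarize a haplotypic expression matrix
#'
#' @param mat A `hap_matrix` (usually coverage-filtered).
#' @return A list with `n_genes` (genes with any data), `n_samples`,
#'   `median_samples_per_gene`, and tibbles `per_gene` (samples with data
#'   per gene) and `per_sample` (genes with data per sample). Invariant to
#'   row/column order.
#' @export
summarize_hap_matrix <- function(mat) {
  df <- as_tibble(mat)
  if (nrow(df) == 0) {
    warn("empty haplotypic expression matrix")
    return(list(n_genes = 0L, n_samples = 0L,
                median_samples_per_gene = 0,
                per_gene = tibble(gene_id = character(), n_samples = integer()),
                per_sample = tibble(sample_id = character(),
                                    n_genes = integer())))
  }
  per_gene <- df |>
    count(.data$gene_id, name = "n_samples") |>
    arrange(.data$gene_id)
  per_sample <- df |>
    count(.data$sample_id, name = "n_genes") |>
    arrange(.data$sample_id)
  list(n_genes = nrow(per_gene),
       n_samples = nrow(per_sample),
       median_samples_per_gene = median(per_gene$n_samples),
       per_gene = per_gene,
       per_sample = per_sample)
}
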