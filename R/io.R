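#' Coordinate conversion between VCF and internal conventions
#'
#' Internally all interval arithmetic uses 0-based half-open coordinates;
#' VCF positions are 1-based. These helpers convert single positions at the
#' boundary and are exact inverses of each other.
#'
#' @param pos Integer vector of 1-based VCF positions.
#' @param pos0 Integer vector of 0-based internal positions.
#' @return Integer vector of converted positions.
#' @export
vcf_to_internal <- function(pos) {
  stopifnot(all(pos >= 1L))
  as.integer(pos) - 1L
}

#' @rdname vcf_to_internal
#' @export
internal_to_vcf <- function(pos0) {
  stopifnot(all(pos0 >= 0L))
  as.integer(pos0) + 1L
}

valid_snp_alleles <- function(x) x %in% c("A", "C", "G", "T")

new_phased_gt <- function(df) {
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "sample_id",
           "h1", "h2", "phased")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("phased genotype table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  structure(as_tibble(df), class = c("phased_gt", class(as_tibble(df))))
}

#' Read phased genotypes from a VCF
#'
#' Parses the GT field of a VCF into a long table with one row per variant
#' per sample. Only biallelic SNPs are retained; indels and other non-SNP
#' records are dropped with a message, and multi-allelic records are a hard
#' error because downstream allele orientation is undefined for them.
#' Genotypes written with the `/` separator are kept but marked unphased;
#' `.` alleles become missing entries.
#'
#' @param path Path to a VCF (optionally gzipped) with GT in FORMAT.
#' @param samples Optional character vector restricting to a subset of the
#'   header samples; an error lists any requested sample absent from the file.
#' @return A tibble of class `phased_gt` with columns `variant_id`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `sample_id`, `h1`, `h2` (0 = ref allele,
#'   1 = alt allele, `NA` = missing) and `phased`.
#' @export
read_phased_vcf <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records")
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    bad <- which(grepl(",", fix$ALT, fixed = TRUE))[1]
    abort(paste0("multi-allelic record at ", fix$CHROM[bad], ":",
                 fix$POS[bad],
                 "; split or drop multi-allelic sites before import"))
  }
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    valid_snp_alleles(fix$REF) & valid_snp_alleles(fix$ALT)
  if (any(!is_snp)) {
    message(sum(!is_snp), " non-SNP record(s) dropped")
  }
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_mat)) abort("VCF has no GT field")
  gt_mat <- gt_mat[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  if (nrow(fix) == 0) abort("no biallelic SNP records in VCF")

  all_samples <- colnames(gt_mat)
  if (!is.null(samples)) {
    absent <- setdiff(samples, all_samples)
    if (length(absent) > 0) {
      abort(paste0("samples not in VCF header: ",
                   paste(absent, collapse = ", ")))
    }
    gt_mat <- gt_mat[, samples, drop = FALSE]
    all_samples <- samples
  }

  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS, "_", fix$REF, "_", fix$ALT),
                fix$ID)

  gt_chr <- as.vector(gt_mat)
  ok <- is.na(gt_chr) | grepl("^[01.]([/|])[01.]$", gt_chr)
  if (any(!ok)) {
    bad <- which(!ok)[1]
    v <- (bad - 1L) %% nrow(gt_mat) + 1L
    abort(paste0("malformed GT '", gt_chr[bad], "' at variant ", ids[v]))
  }
  a1 <- substr(gt_chr, 1, 1)
  a2 <- substr(gt_chr, 3, 3)
  h1 <- ifelse(is.na(gt_chr) | a1 == ".", NA_integer_, as.integer(a1))
  h2 <- ifelse(is.na(gt_chr) | a2 == ".", NA_integer_, as.integer(a2))
  phased <- !is.na(gt_chr) & substr(gt_chr, 2, 2) == "|"

  out <- tibble(
    variant_id = rep(ids, times = length(all_samples)),
    chrom      = rep(fix$CHROM, times = length(all_samples)),
    pos        = rep(as.integer(fix$POS), times = length(all_samples)),
    ref        = rep(fix$REF, times = length(all_samples)),
    alt        = rep(fix$ALT, times = length(all_samples)),
    sample_id  = rep(all_samples, each = nrow(fix)),
    h1 = h1, h2 = h2,
    phased = phased & !is.na(h1) & !is.na(h2)
  )
  new_phased_gt(out)
}

#' Write phased genotypes to a VCF
#'
#' @param gt A `phased_gt` tibble as returned by [read_phased_vcf()] or
#'   [simulate_genotypes()].
#' @param path Output path; written gzip-compressed (use a `.vcf.gz` suffix).
#' @return `path`, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_phased_vcf <- function(gt, path) {
  vars <- gt |>
    distinct(.data$variant_id, .data$chrom, .data$pos, .data$ref, .data$alt)
  samples <- unique(gt$sample_id)
  wide <- gt |>
    mutate(gt_str = ifelse(
      is.na(.data$h1) | is.na(.data$h2), ".|.",
      paste0(.data$h1, ifelse(.data$phased, "|", "/"), .data$h2))) |>
    select("variant_id", "sample_id", "gt_str") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "gt_str")
  wide <- wide[match(vars$variant_id, wide$variant_id), , drop = FALSE]

  fix <- cbind(CHROM = vars$chrom, POS = as.character(vars$pos),
               ID = vars$variant_id, REF = vars$ref, ALT = vars$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  gt_mat <- cbind(FORMAT = "GT",
                  as.matrix(wide[, samples, drop = FALSE]))
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  obj <- methods::new("vcfR", meta = meta, fix = fix, gt = gt_mat)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

# ---- haplotypic expression matrix ------------------------------------------

#' Construct a haplotypic expression matrix
#'
#' A haplotypic expression matrix holds, for each gene and sample, the number
#' of RNA-seq reads assigned to each of the two haplotypes (A and B). It is
#' stored long: one row per gene-sample cell with data; absent rows are
#' missing cells, which keeps `(0, 0)` distinguishable from "no data". The
#' `gw_phased` attribute records whether haplotype A/B labels are genome-wide
#' consistent with a phased VCF; only genome-wide phased matrices may be
#' joined to genotypes.
#'
#' @param df Data frame with columns `gene_id`, `sample_id`, `hapA`, `hapB`.
#' @param gw_phased Logical; are A/B labels genome-wide phased?
#' @return A tibble of class `hap_matrix`.
#' @export
hap_matrix <- function(df, gw_phased) {
  req <- c("gene_id", "sample_id", "hapA", "hapB")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("hap matrix lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(df$hapA < 0 | df$hapB < 0, na.rm = TRUE)) {
    abort("haplotypic counts must be non-negative")
  }
  if (anyDuplicated(paste(df$gene_id, df$sample_id))) {
    abort("duplicate gene x sample cells in hap matrix")
  }
  out <- as_tibble(df) |>
    mutate(hapA = as.integer(.data$hapA), hapB = as.integer(.data$hapB))
  attr(out, "gw_phased") <- isTRUE(gw_phased)
  class(out) <- c("hap_matrix", class(as_tibble(df)))
  out
}

#' @rdname hap_matrix
#' @param x Object to query.
#' @export
is_gw_phased <- function(x) isTRUE(attr(x, "gw_phased"))

#' Read / write a haplotypic expression matrix TSV
#'
#' On disk the matrix is a wide TSV: one row per gene, one column per sample,
#' cells formatted `"HAP_A_COUNT|HAP_B_COUNT"`, with missing cells encoded as
#' the empty string. The genome-wide-phasing status is carried in a leading
#' `#gw_phased=` comment line. Write-then-read is the identity.
#'
#' @param path File path (plain or gzipped TSV).
#' @return For the reader, a `hap_matrix` tibble.
#' @export
read_hap_matrix <- function(path) {
  first <- readLines(path, n = 1)
  gw <- FALSE
  skip <- 0L
  if (grepl("^#gw_phased=", first)) {
    gw <- tolower(sub("^#gw_phased=", "", first)) %in% c("true", "1", "yes")
    skip <- 1L
  }
  wide <- readr::read_tsv(path, skip = skip, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (names(wide)[1] != "gene_id") {
    abort("hap matrix must have a leading gene_id column")
  }
  long <- wide |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "cell") |>
    filter(!is.na(.data$cell) & .data$cell != "")
  bad <- !grepl("^\\d+\\|\\d+$", long$cell)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0("malformed cell '", long$cell[i], "' at gene ",
                 long$gene_id[i], ", sample ", long$sample_id[i]))
  }
  parts <- stringr::str_split_fixed(long$cell, stringr::fixed("|"), 2)
  hap_matrix(
    tibble(gene_id = long$gene_id, sample_id = long$sample_id,
           hapA = as.integer(parts[, 1]), hapB = as.integer(parts[, 2])),
    gw_phased = gw
  )
}

#' @rdname read_hap_matrix
#' @param mat A `hap_matrix`.
#' @export
write_hap_matrix <- function(mat, path) {
  wide <- mat |>
    as_tibble() |>
    mutate(cell = paste0(.data$hapA, "|", .data$hapB)) |>
    select("gene_id", "sample_id", "cell") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cell",
                       values_fill = "")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#gw_phased=", tolower(as.character(is_gw_phased(mat)))),
             con)
  writeLines(paste(names(wide), collapse = "\t"), con)
  if (nrow(wide) > 0) {
    body <- apply(as.matrix(wide), 1, paste, collapse = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

# ---- SNP-level allele-count tables -----------------------------------------

snp_required_cols <- c("chrom", "pos", "ref", "alt", "refCount", "altCount")

#' Read / write SNP-level allele-count tables
#'
#' Reads allele counts at heterozygous SNPs in the tab-separated layout
#' produced by per-site allele counters (columns `chrom`, `pos`, `ref`,
#' `alt`, `refCount`, `altCount`, optional `otherCount`, `sample_id`,
#' `tissue_id`, plus any annotation columns, which round-trip). A missing
#' `otherCount` column defaults to zero.
#'
#' @param path File path.
#' @return A tibble with one row per site (columns renamed to snake case:
#'   `ref_count`, `alt_count`, `other_count`).
#' @export
read_snp_counts <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  missing_cols <- setdiff(snp_required_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("SNP count table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df |>
    rename(ref_count = "refCount", alt_count = "altCount")
  if ("otherCount" %in% names(df)) {
    df <- rename(df, other_count = "otherCount")
  } else {
    df$other_count <- 0L
  }
  if (any(df$ref_count < 0 | df$alt_count < 0 | df$other_count < 0)) {
    abort("allele counts must be non-negative")
  }
  df |>
    mutate(pos = as.integer(.data$pos),
           ref_count = as.integer(.data$ref_count),
           alt_count = as.integer(.data$alt_count),
           other_count = as.integer(.data$other_count))
}

#' @rdname read_snp_counts
#' @param records Tibble of SNP allele-count records.
#' @export
write_snp_counts <- function(records, path) {
  out <- records |>
    rename(refCount = "ref_count", altCount = "alt_count",
           otherCount = "other_count")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# ---- gene annotation -------------------------------------------------------

#' Read a BED6-style gene annotation
#'
#' Expects columns chrom, start (0-based), end, gene_id, gene_type, strand.
#' The transcription start site (TSS) is derived from strand: the interval
#' start on `+`, `end - 1` on `-`, in 0-based coordinates.
#'
#' @param path File path to a headerless BED6-like TSV.
#' @return Tibble with columns `gene_id`, `gene_type`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open) and `tss` (0-based).
#' @export
read_gene_bed <- function(path) {
  df <- readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "gene_id", "gene_type",
                        "strand"),
    col_types = "ciiccc", progress = FALSE)
  gene_annotation(df)
}

#' @rdname read_gene_bed
#' @param df Data frame with the BED6-style columns above.
#' @export
gene_annotation <- function(df) {
  if (any(df$start >= df$end)) {
    abort("gene interval start must be < end")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  as_tibble(df) |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L)) |>
    select("gene_id", "gene_type", "chrom", "strand", "start", "end", "tss")
}

#' Read a regulatory-variant list
#'
#' A TSV with header columns `chrom`, `pos` (1-based), `ref`, `alt`,
#' `gene_id`, and optionally `class` (e.g. `top` / `independent` for eQTL
#' masking) and `variant_id`.
#'
#' @param path File path.
#' @return Tibble of regulatory variants.
#' @export
read_variant_list <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "gene_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("variant list lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"variant_id" %in% names(df)) {
    df$variant_id <- paste0(df$chrom, "_", df$pos, "_", df$ref, "_", df$alt)
  }
  mutate(df, pos = as.integer(.data$pos))
}

#' @rdname read_variant_list
#' @param variants Tibble of regulatory variants.
#' @export
write_variant_list <- function(variants, path) {
  readr::write_tsv(variants, path, progress = FALSE)
  invisible(path)
}
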