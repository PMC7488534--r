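library(dplyr)

# three-sample, two-gene phased genotype fixture used across tests
tiny_gt <- function() {
  haploAE:::new_phased_gt(tibble::tribble(
    ~variant_id, ~chrom, ~pos, ~ref, ~alt, ~sample_id, ~h1, ~h2, ~phased,
    "v1", "chr1", 1500L, "A", "G", "S1", 0L, 1L, TRUE,
    "v1", "chr1", 1500L, "A", "G", "S2", 1L, 0L, TRUE,
    "v1", "chr1", 1500L, "A", "G", "S3", 1L, 1L, TRUE,
    "v2", "chr1", 5000L, "C", "T", "S1", 0L, 0L, TRUE,
    "v2", "chr1", 5000L, "C", "T", "S2", 0L, 1L, FALSE,
    "v2", "chr1", 5000L, "C", "T", "S3", NA, NA, FALSE
  ))
}

tiny_mat <- function(gw = TRUE) {
  hap_matrix(tibble::tribble(
    ~gene_id, ~sample_id, ~hapA, ~hapB,
    "G1", "S1", 10L, 30L,
    "G1", "S2", 10L, 30L,
    "G1", "S3", 10L, 30L,
    "G2", "S1", 20L, 20L,
    "G2", "S2", 5L, 2L
  ), gw_phased = gw)
}

tiny_genes <- function() {
  gene_annotation(tibble::tribble(
    ~chrom, ~start, ~end, ~gene_id, ~gene_type, ~strand,
    "chr1", 999L, 2000L, "G1", "protein_coding", "+",
    "chr1", 1800L, 6000L, "G2", "protein_coding", "-"
  ))
}

write_tiny_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("chr1", "1500", "v1", "A", "G", ".", "PASS", ".", "GT",
          "0|1", "1|0", "1|1", sep = "\t"),
    paste("chr1", "5000", "v2", "C", "T", ".", "PASS", ".", "GT",
          "0|0", "0/1", "./.", sep = "\t")
  ), path)
  path
}

# independent oracle: exact two-sided binomial p by exhaustive enumeration of
# all 2^n read sequences (no dbinom), minimum-likelihood two-sided rule
enum_binom_two_sided <- function(x, n, p0) {
  seqs <- expand.grid(rep(list(c(0, 1)), n))
  k <- rowSums(seqs)
  pr <- p0^k * (1 - p0)^(n - k)
  p_k <- vapply(0:n, function(kk) sum(pr[k == kk]), numeric(1))
  sum(p_k[p_k <= p_k[x + 1] * (1 + 1e-7)])
}

# brute-force BH q-values straight from the step-up definition
brute_bh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- sum(p <= p[i])
    candidates <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) {
        rank_j <- sum(p <= p[j])
        m * p[j] / rank_j
      } else Inf
    }, numeric(1))
    q[i] <- min(1, min(candidates))
  }
  q
}
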