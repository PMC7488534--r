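Package: haploAE
Title: Population-Scale Haplotype-Level Allelic Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing allelic expression (AE) at the haplotype
    level across cohorts of RNA-seq samples. Aggregates per-sample gene-level
    haplotypic read counts into population matrices, phases regulatory
    variants (e.g. eQTLs) with haplotypic counts to estimate cis-regulatory
    effect sizes as allelic fold change (aFC) with confidence intervals and
    heterozygote-versus-homozygote rank-sum tests, annotates SNP-level
    allele-count tables with gene assignments, reference-bias-aware binomial
    imbalance tests, per-tissue FDR and quality flags, tests gene-by-sample
    allelic imbalance with eQTL-heterozygote masking, and models allelic
    imbalance as a function of promoter-proximal heterozygous variant counts
    stratified by minor allele frequency. Includes a seeded synthetic-cohort
    simulator (phased genotypes, haplotypic counts, SNP-level counts and
    ground truth) so every stage can be exercised and calibrated without
    protected genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
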