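---
title: "Methods: haplotype-level allelic expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-level allelic expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Problem and data model

RNA sequencing of a diploid individual measures both gene copies at once.
When reads can be assigned to a parental haplotype through heterozygous
sites, the two copies can be quantified separately, and the ratio between
them — allelic expression (AE) — is a within-individual readout of
cis-acting regulatory variation that cancels environment and trans effects.

haploAE works with two complementary representations:

* a **SNP-level allele-count table**: per heterozygous site, per sample and
  tissue, the read counts supporting the reference allele, alternative
  allele, and any other base;
* a **haplotypic expression matrix**: per gene and sample, total read counts
  assigned to haplotype A and haplotype B after aggregating all heterozygous
  sites of the gene through phasing.

The matrix form is the analysis substrate for everything downstream. Its
orientation contract is central: a matrix is usable for cross-variant
analyses only if it is **genome-wide phased**, meaning haplotype A of every
gene in a sample is the same physical chromosome, and corresponds to the
first allele (`h1`) of that sample's phased genotypes. `run_cis_var()`
refuses matrices without the genome-wide-phased flag as a hard error, since
with per-gene phasing the A/B labels are arbitrary and any signed statistic
joining the VCF to the matrix would be meaningless.

## Coordinates and formats

Internally all gene and interval coordinates are 0-based half-open (BED
convention); VCF positions are converted to and from 1-based at the I/O
boundary only. The transcription start site (TSS) of a gene on the `+`
strand is its interval start; on the `-` strand it is `end - 1` (0-based).
Missing matrix cells are absent rows in the long in-memory form and empty
strings in the wide on-disk form (`HAP_A|HAP_B` cells, a `#gw_phased=`
header comment carries the phasing flag).

## Per-sample and per-variant effect sizes

The per-sample allelic fold change between the haplotype carrying the
alternative allele and the one carrying the reference allele is

    aFC = log2((alt_hap_count + 1) / (ref_hap_count + 1))

with a +1 pseudocount so zero counts remain finite. For heterozygous
samples the counts are oriented through the phased genotype (`h1 == 1`
means the alternative allele sits on haplotype A). For homozygous samples
orientation is undefined, so the reported `afc` is the absolute value of
the unoriented ratio, with the signed unoriented value kept in
`afc_unoriented`.

Each per-sample aFC carries an exact binomial-proportion
(Clopper–Pearson) 95% interval mapped through the aFC formula. The
variant-level effect size is the **median aFC across heterozygotes**, with
a seeded percentile bootstrap interval (default 1000 replicates; the
resampled values are sorted before the quantile step so the interval does
not depend on sample order).

A true regulatory variant should produce larger absolute imbalance in
carriers (heterozygotes) than in non-carriers (homozygotes). This is
tested with a one-sided Mann–Whitney rank-sum test of |aFC| in
heterozygotes versus homozygotes via `stats::wilcox.test(alternative =
"greater")`. We deliberately use the normal approximation with continuity
correction uniformly rather than switching to the exact distribution at
small n: group sizes in cohort use are far past the asymptotic regime, and
one uniform rule keeps p-values comparable across variants.

### Known bias of the pseudocount estimator

The +1 pseudocount shrinks each sample's ratio toward 1, so the median-aFC
estimator is attenuated toward zero, more strongly for large effects and
low coverage. At the package's default coverage model (negative binomial,
mean 100, size 5) the attenuation is negligible below 1 log2 unit but
approaches ~0.1 log2 units at a true effect of 2. This is a property of
the estimator, not a bug; we keep the estimator as defined because it is
the field convention and robust at zero counts.

## SNP-level annotation and testing

`annotate_snp_ae()` runs the site-level quality pipeline:

1. gene assignment by genomic overlap (sites in two genes yield one record
   per gene; intergenic sites get `NA`);
2. flags: `flag_low_mappability` (overlap with a low-mappability BED),
   `flag_mapping_bias` (membership in a blacklist of positions shown
   biased in upstream read simulations — this package consumes such a
   list, it does not simulate reads);
3. a null reference ratio per ordered (ref, alt) allele pair, the median
   reference fraction over unflagged, covered sites, used only when the
   pair has at least 200 sites (otherwise 0.5) — this absorbs alignment
   reference bias;
4. an exact two-sided binomial test of each site against its pair's null
   ratio, Benjamini–Hochberg corrected per tissue;
5. a genotyping-error screen: for each site the one-sided probability of
   seeing at least the observed minor-allele reads under pure sequencing
   noise, Binomial(coverage, epsilon). Sites *not* significant after BH at
   1% FDR get `flag_genotype_warning` — their "heterozygosity" is
   indistinguishable from a homozygote plus noise. The noise rate epsilon
   defaults to 0.005 and can be estimated from the data as
   `sum(other) / sum(ref + alt + other)`.

The two-sided binomial p-value uses the minimum-likelihood inclusion rule
(sum of all outcome probabilities not exceeding the observed one, with a
1 + 1e-7 tie tolerance), the same convention as `stats::binom.test`, but
vectorized by grouping on (n, p0) and using a sorted-pmf cumulative sum,
which makes matrix-scale testing feasible.

## Gene-level imbalance and eQTL masking

`test_imbalance()` applies the exact two-sided binomial test against 0.5
to every (gene, sample) cell of a coverage-filtered matrix and corrects by
BH. The default correction universe is **all cells jointly**; a gene-level
alternative (Bonferroni within gene on the minimum p, BH across genes) is
exposed via `level = "gene"` since both conventions are defensible and the
choice changes counts.

To ask how much imbalance is explained by known common regulatory
variants, `build_eqtl_het_mask()` marks every (gene, sample) where the
sample is heterozygous for **any** listed eQTL of the gene, and
`mask_hap_matrix()` removes those cells. Comparing imbalanced-gene counts
before and after masking (``count_imbalanced_genes()``, at a minimum
number of significant samples per gene — we use 3 in the shipped
analyses so that a gene requires recurrent signal) quantifies the residual
imbalance attributable to unlisted, typically rare, regulatory variation.
Significance is recomputed on the masked matrix rather than subset from
the unmasked results, so the multiple-testing universe matches the data
actually analyzed.

## Promoter rare-variant model

For each (gene, sample), heterozygous variants in the 10 kb window
upstream of the TSS (strand-aware: `(TSS-10kb, TSS]` on `+`, `[TSS,
TSS+10kb)` on `-`) are counted in five minor-allele-frequency bins,
lower-inclusive, upper-exclusive, top bin closed at 0.5:

    [0.10, 0.50]  [0.05, 0.10)  [0.01, 0.05)  [0.005, 0.01)  (0, 0.005)

The response is the median across tissues of the absolute haplotypic
log-ratio |log2((hapA+1)/(hapB+1))|. `fit_promoter_model()` fits ordinary
least squares with an intercept and t-based 95% intervals, refusing
rank-deficient designs by naming the collinear columns. Rows with zero
het promoter variants are retained — they identify the intercept and the
contrast is *against* them. Increasing coefficients from common to rare
bins indicate that rarer promoter variants carry larger regulatory
effects, consistent with selection against large-effect common variants.

## Simulator

`simulate_cohort()` generates cohorts whose generative assumptions match
what the methods assume, no more: Hardy–Weinberg phased genotypes;
additive log2 haplotype effects (`p_hapA = 2^A1 / (2^A1 + 2^A2)`);
negative-binomial total coverage (mean 100, size 5 by default);
beta-binomial allelic counts with overdispersion `rho` (binomial at 0);
logit-scale reference bias; and injected genotyping errors (homozygotes
mislabeled heterozygous whose minor reads are pure noise). Scenario
presets: `null`, `single-eqtl`, `rare-promoter` (the design matrix is
emitted directly under the linear-Gaussian model `y = 0.1 + X beta +
N(0, 0.5^2)` with bin effects 0.05/0.08/0.12/0.2/0.3), `genotype-errors`,
and `eqtl-mask` (all genes driven; 80% of drivers listed by default).
Seeds are mandatory and the global RNG state is preserved across calls.

Cohort sizes used in the shipped analyses (200–250 samples, up to 500
genes) were chosen to keep Monte-Carlo error well inside the assertion
tolerances while running in minutes.

## Limitations

* The simulator does not model read alignment; mapping bias enters only
  as a consumed blacklist or a logit shift, not as simulated reads.
* Tissue structure is i.i.d. replication — no cross-tissue correlation.
* The rank-sum test's exact small-sample distribution is not used (see
  above); p-values at very small group counts are approximate.
* The pseudocount attenuation of median aFC at large effects is
  documented above and not corrected.
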