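# haploAE

Haplotype-level allelic expression (AE) analysis for phased RNA-seq
cohorts.

## Scientific problem

RNA sequencing of a diploid sample measures both gene copies together.
When reads overlap heterozygous sites and genotypes are phased genome-wide,
the reads can be split by parental haplotype, giving per-gene counts for
haplotype A and haplotype B in every individual. The ratio between the two
— allelic expression — isolates *cis*-acting regulation within an
individual, cancelling environmental and *trans* effects.

haploAE implements the population-scale analyses built on such haplotypic
count matrices:

* **Effect sizes of regulatory variants** (`run_cis_var()`): for a variant
  paired with a gene, the per-sample allelic fold change
  `aFC = log2((alt_hap + 1) / (ref_hap + 1))`, oriented through the phased
  genotype; the median across heterozygotes with a bootstrap confidence
  interval; and a one-sided rank-sum test that carriers (heterozygotes)
  show larger absolute imbalance than non-carriers (homozygotes).
* **Gene-level allelic imbalance** (`test_imbalance()`): exact binomial
  tests of every gene × sample cell against a balanced 0.5 ratio with
  Benjamini–Hochberg correction, plus masking of cells heterozygous for
  known eQTLs (`build_eqtl_het_mask()`, `mask_hap_matrix()`) to quantify
  imbalance left unexplained by known common regulatory variants.
* **SNP-level AE quality pipeline** (`annotate_snp_ae()`): gene
  assignment, low-mappability and mapping-bias flags, allele-pair null
  reference ratios, exact binomial AE tests, and a genotyping-error screen
  that flags "heterozygous" sites whose minor-allele reads are consistent
  with pure sequencing noise.
* **Promoter rare-variant model** (`build_promoter_design()`,
  `fit_promoter_model()`): absolute haplotypic imbalance regressed on
  counts of heterozygous promoter-proximal variants in five
  minor-allele-frequency bins, testing whether rarer variants carry larger
  regulatory effects.
* **A seeded cohort simulator** (`simulate_cohort()`) with scenario
  presets (`null`, `single-eqtl`, `rare-promoter`, `genotype-errors`,
  `eqtl-mask`) matching the generative assumptions of the methods, plus
  readers/writers for phased VCFs (via vcfR), haplotypic count matrices,
  SNP count tables and gene BEDs.

All functions take and return tibbles; fitted objects support
`tidy()`/`glance()` and `autoplot()`.

## Worked example

```r
library(haploAE)

# a cohort of 100 individuals, 3 genes, one cis-eQTL per gene with a
# true effect of 1 log2 unit
sim <- simulate_cohort("single-eqtl",
                       sim_config(n_samples = 100, n_genes = 3,
                                  afc = 1, seed = 42))

res <- run_cis_var(sim$eqtl_list, sim$genotypes,
                   filter_hap_matrix(sim$matrices[[1]]), seed = 42)
res
#> cis-regulatory variant aFC estimates
#>  variants scored: 3  skipped: 0
#> # A tibble: 3 × 9
#>   variant_id    gene_id  n_het n_hom median_afc median_afc_lo median_afc_hi
#>   <chr>         <chr>    <int> <int>      <dbl>         <dbl>         <dbl>
#> 1 GENE0001_eqtl GENE0001    49    50      1.07          1.01           1.17
#> 2 GENE0002_eqtl GENE0002    38    62      0.926         0.665          1.09
#> 3 GENE0003_eqtl GENE0003    41    59      1.06          0.982          1.15
#> # ℹ 2 more variables: median_abs_afc_hom <dbl>, ranksum_p <dbl>

head(test_imbalance(filter_hap_matrix(sim$matrices[[1]])), 3)
#> # A tibble: 3 × 7
#>   gene_id  sample_id  hapA  hapB  p_value  q_value significant
#>   <chr>    <chr>     <int> <int>    <dbl>    <dbl> <lgl>
#> 1 GENE0001 S001         23    29 0.488    0.695    FALSE
#> 2 GENE0002 S001         68    54 0.239    0.426    FALSE
#> 3 GENE0003 S001         33     8 0.000112 0.000860 TRUE

# rarer promoter variants carry larger effects
simp <- simulate_cohort("rare-promoter",
                        sim_config(n_samples = 250, n_genes = 20, seed = 7))
fit_promoter_model(simp$design)
#> promoter MAF-bin linear model (5000 individual x gene rows)
#> # A tibble: 6 × 5
#>   term           estimate std_error conf_low conf_high
#>   <chr>             <dbl>     <dbl>    <dbl>     <dbl>
#> 1 (Intercept)      0.0958   0.0140    0.0683    0.123
#> 2 bin_0.50_0.10    0.0555   0.00732   0.0411    0.0698
#> 3 bin_0.10_0.05    0.0819   0.0104    0.0615    0.102
#> 4 bin_0.05_0.01    0.130    0.0167    0.0977    0.163
#> 5 bin_0.01_0.005   0.185    0.0306    0.125     0.245
#> 6 bin_0.005_0      0.287    0.0604    0.169     0.406
```

A thin command-line front end over the same functions ships in
`inst/cli/haploae.R`:

```sh
Rscript inst/cli/haploae.R simulate --scenario single-eqtl --n-samples 100 \
  --n-genes 5 --seed 3 --out demo
Rscript inst/cli/haploae.R cis-var --vcf demo/sim.vcf.gz \
  --matrix demo/matrix_tissue1.gw_phased.txt.gz \
  --variants demo/eqtls.tsv --out demo/cis.tsv
```

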