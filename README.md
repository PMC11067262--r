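# hlapheno

Population-scale analysis of classical HLA variation from SNP array data.

The human leukocyte antigen (HLA) genes in the MHC region of chromosome 6
(28,510,120–33,480,577 bp on GRCh38) are the most polymorphic loci in the
genome and drive susceptibility to autoimmune disease, infection and severe
adverse drug reactions. Directly typing HLA alleles by sequencing is too
expensive for biobank-scale cohorts, but the dense SNP haplotypes around
each gene tag its alleles well enough that they can be *imputed* from array
genotypes. `hlapheno` implements the full analysis chain around that idea,
for statistical geneticists working with cohort array data plus a typed
reference subset:

1. **QC and region extraction** — variant filters (call rate ≥ 0.98,
   MAF ≥ 0.05, exact Hardy–Weinberg p ≥ 1e-6), sample filters (call rate,
   heterozygosity ±3 SD, method-of-moments relatedness ≤ 0.1875), MHC
   windowing; VCF and PLINK bed/bim/fam input/output.
2. **Attribute-bagging HLA imputation** — an ensemble of classifiers, each
   trained on a bootstrap sample with a greedily grown SNP subset from the
   gene's 500 kb flank. A classifier's parameter is a frequency table over
   joint (SNP-haplotype pattern, HLA allele) haplotypes fitted by EM on
   unphased data; imputation averages per-classifier posteriors over
   unordered allele pairs and calls a genotype when the posterior reaches
   the threshold (default 0.5). Accuracy is validated internally on a 7:3
   train/validation split, scored per allele.
3. **Variant encoding** — HLA-allele dosages at 2/4/6-digit resolution,
   translation of 4-digit alleles to protein sequences, per-residue
   biallelic variants (`HLA-B-Q94`) and multiallelic amino-acid positions,
   post-imputation QC (missing rate ≤ 0.05; MAF ≥ 0.01 for biallelic HLA
   variants), and LD-based gene assignment (r² ≥ 0.7).
4. **PheWAS** — additive logistic regression for binary traits (Firth
   fallback under separation); for quantitative traits, covariate
   residualization, rank-based inverse-normal transform (Blom), then OLS on
   the dosage. Multiallelic positions use an omnibus likelihood-ratio test:
   2(ℓ₁ − ℓ₀) ~ χ² with n − 1 degrees of freedom for n residues. Covariates
   are sex, age, age², and the top 10 PCs; significance at p < 5×10⁻⁸.
5. **Forward conditional fine-mapping** — iteratively conditions on each
   top signal *plus all HLA alleles and amino-acid polymorphisms in LD
   (r² ≥ 0.7) with it*, until no genome-wide-significant signal remains;
   complete-LD (r² = 1) companions are reported alongside.
6. **Heritability** — Haseman–Elston regression of phenotype cross-products
   y_i·y_j on GRM entries over subject pairs (univariate h²; bivariate
   genetic covariance, r_g = cov_g/√(h²₁h²₂)), block-jackknife SEs, and a
   Benjamini–Hochberg FDR-filtered genetic-correlation network.
7. **Haplotype frequencies** — EM over unphased multilocus typings with
   progressive gene insertion, for ranked 5- and 8-gene haplotype tables.
8. **Pharmacogenomics** — carrier counts, carrier percentages and allele
   frequencies for a curated list of ADR-associated alleles
   (HLA-B\*58:01/allopurinol, HLA-B\*15:02/carbamazepine, ...), with
   Hardy–Weinberg expected carrier fractions (1 − (1 − p)²) as a
   consistency diagnostic.

Because real biobank data of this kind is access-controlled, the package
ships a synthetic-cohort generator (`simulate_reference_pool()`,
`simulate_cohort()`, `simulate_phenotypes()`, `make_aa_table()`) that
reproduces the statistical structure the chain relies on — SNP haplotypes
in tunable LD with multi-gene HLA alleles at realistic frequencies, and
additive HLA effects on binary and quantitative traits — so every stage is
testable end to end without any download.

## Worked example

```r
library(hlapheno)

pool   <- simulate_reference_pool(n_haplotypes = 1000, n_snps = 30,
                                  alleles_per_gene = c(4, 4),
                                  tagging_strength = 0.95, seed = 7)
cohort <- simulate_cohort(pool, n_subjects = 1000, seed = 8)

val <- hla_internal_validation(cohort$genotypes, cohort$typing,
                               gene = "HLA-A", resolution = 4,
                               train_fraction = 0.7, n_classifiers = 10,
                               seed = 9)
#> HLA-A 4-digit: accuracy 98.7%, call rate 92.3% (train 700 / validation 300)

calls <- predict(val$model, cohort$genotypes, call_threshold = 0.5)
head(calls, 3)
#>   sample  gene allele1 allele2 posterior called
#> 1 S00001 HLA-A A*02:01 A*03:01 0.9586464   TRUE
#> 2 S00002 HLA-A A*01:01 A*02:01 0.9700996   TRUE
#> 3 S00003 HLA-A A*01:01 A*03:01 0.9622994   TRUE

carrier_report(calls, c("A*01:01", "A*04:01"))
#>    allele carriers carrier_pct allele_freq n_called hwe_expected_pct
#> 1 A*01:01      613       65.56      0.4096      935            65.15
#> 2 A*04:01      181       19.36      0.1037      935            19.67

top_haplotypes(em_haplotype_frequencies(cohort$typing,
                                        genes = c("HLA-A", "HLA-C")), 3)
#>   rank       haplotype frequency cumulative
#> 1    1 A*01:01-C*01:01 0.1708669  0.1708669
#> 2    2 A*01:01-C*02:01 0.1171218  0.2879886
#> 3    3 A*02:01-C*01:01 0.1170031  0.4049917
```

The validation line reads: with SNP–allele tagging of 0.95, the
attribute-bagging ensemble recovers 98.7% of held-out 4-digit alleles among
the 92.3% of validation subjects whose best posterior clears the 0.5 call
threshold. The carrier report shows the observed carrier percentages
agreeing with their Hardy–Weinberg expectations, as they should under
random haplotype union.

`run_pipeline(run_config(...))` chains all stages (simulate → qc → train →
impute → encode → phewas → conditional → heritability → haplotypes → pgx)
under one seed and writes per-stage outputs plus a digest manifest.

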