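---
title: "Methods: HLA imputation and MHC-wide phenotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA imputation and MHC-wide phenotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `hlapheno`: the models
and their assumptions, the parameters that matter, the numerical choices,
and what the bundled synthetic data can and cannot establish.

## The imputation model

### Setup

For one classical HLA gene at a fixed field resolution (2, 4 or 6 digits),
the data are unphased SNP dosages $g_{ij} \in \{0,1,2\}$ in the gene's
flanking window and, for training subjects, the unordered allele pair
$\{a_i^{(1)}, a_i^{(2)}\}$. The model assumes the standard haplotype logic
of the MHC: each physical chromosome carries one HLA allele *and* one SNP
haplotype, and the pair is informative because recombination within the
window is rare. The joint object being estimated is a frequency table
$f(s, a)$ over (SNP-subset haplotype pattern $s$, HLA allele $a$), under
random union of haplotypes (Hardy–Weinberg at the haplotype level).

### Attribute bagging

A single frequency table over many SNPs would overfit badly at realistic
reference sizes (hundreds of subjects). The ensemble therefore trains many
small classifiers (default `n_classifiers = 100`, matching common practice
for this estimator family; the test suite and acceptance preset scale this
to 20 to keep desk runtimes in minutes — accuracy on the synthetic preset
is insensitive to the reduction):

* each classifier draws a bootstrap sample of training subjects;
* its SNP subset is grown greedily: at every step `mtry` candidate SNPs
  (default $\lceil\sqrt{m}\rceil$ of the $m$ flank SNPs, the usual
  random-subspace default) are scored by out-of-bag per-allele prediction
  accuracy, and the best is kept while accuracy does not decrease, up to
  `max_snps = 15` — the cap bounds the EM state space, and on tag-SNP
  architectures the greedy path finds the signature SNPs long before it;
* given the subset, $f(s,a)$ is fitted by EM over the unphased bootstrap
  data (phase is the only latent variable at training time, since alleles
  are observed).

During candidate scoring the EM runs with a loose tolerance (1e-4, 60
iterations); the selected subset is refitted to convergence (1e-7, 500
iterations). Frequencies below 1e-8 are pruned and the table renormalized.

### Prediction

For a subject with dosages $g$ at a classifier's SNPs, the posterior over
unordered allele pairs is

$$P(\{a_1,a_2\} \mid g) \propto \sum_{(s_1,s_2)} f(s_1,a_1)f(s_2,a_2)
  \,\varepsilon^{\,d(s_1+s_2,\,g)}$$

where $d$ counts allele mismatches between the implied and observed
genotype over non-missing SNPs and $\varepsilon = 0.01$ per mismatch. The
penalty term keeps genotype patterns absent from the (finite) training
table from receiving zero mass — with exact matching only, a single
unobserved haplotype pattern would make a subject uncallable; missing
genotypes contribute no mismatch, which marginalizes them over the table.
Posteriors are averaged across classifiers; the argmax pair (ties broken
lexicographically) is called when its averaged posterior reaches
`call_threshold = 0.5`. Lowering the threshold can only add calls, so call
rate is monotone in it.

Internal validation splits subjects `round(0.7 n)` : rest, trains on the
first part and scores the second. Accuracy is **per allele**: each called
subject contributes two comparisons under the best matching of unordered
pairs, so a half-right heterozygote scores 1/2. This convention is stated
explicitly in the validation output because "imputation accuracy" is
ambiguous between per-allele and per-genotype conventions; per-allele is
the convention of the estimator family this model follows.

## The association engine

Binary traits use additive logistic regression with covariates sex, age,
age², PC1–PC10. Wald tests are reported; when the ML fit fails (perfect
separation or non-convergence, which is routine for rare alleles crossed
with rare traits), the fit falls back to Firth's penalized likelihood
(Jeffreys-prior score adjustment, Newton iterations with step halving) and
the result is flagged `method = "firth"`.

Quantitative traits are processed in three stages: OLS on the covariates,
rank-based inverse-normal transform of the residuals — Blom offsets,
$\Phi^{-1}((r - 3/8)/(n + 1/4))$, average ranks for ties — then OLS of the
transformed residuals on the dosage. The transform makes the test
invariant to any monotone rescaling of the raw trait and makes effect
sizes comparable across traits (SD units).

Multiallelic amino-acid positions are tested with an omnibus LRT: the full
model adds the dosages of all residues except the reference (most
frequent; ties lexicographic) to the null model's covariates, and
$2(\ell_1-\ell_0) \sim \chi^2_{n-1}$ for $n$ residues. For quantitative
traits the LRT is computed on the same transformed residuals as the
biallelic scan ($n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$), so the two test
families share a null model; collinear residue columns are dropped with a
warning and the df reduced. Significance uses the conventional
genome-wide $5\times10^{-8}$ line with no further multiplicity correction,
matching standard PheWAS reporting of this region.

The single-variant tests are plain covariate-adjusted regressions. A
whole-genome ridge/LOCO pre-adjustment (as in REGENIE-style pipelines) is
deliberately not reproduced: the package analyses only the MHC window, so
there is no leave-one-chromosome-out genome to build the predictor from.

## Conditional fine-mapping

LD in the MHC makes marginal hits redundant. The forward procedure tests
all remaining variants conditioning on the accumulated covariate set,
stops when min p ≥ 5×10⁻⁸, and otherwise selects the top variant and adds
it **plus every HLA allele and amino-acid polymorphism with r² ≥ 0.7 to
it** as covariates. Conditioning on the LD-linked HLA polymorphisms (and
not merely the top variant) is the point of the modified procedure: it
removes the whole signal attributable to the underlying HLA gene rather
than the single proxy. SNV/indel companions are reported but not
conditioned on, and variants in complete LD (r² = 1, tolerance 1e-12)
with a selected signal are listed as co-top signals. For quantitative
traits the residualization is done once and conditioning dosages enter the
stage-3 regression, keeping the null fixed across iterations; LD for
companion sets is computed in all subjects. A `max_iter = 20` guard bounds
pathological inputs.

## Heritability and genetic correlation

The GRM standardizes each dosage column by its observed allele frequency
($x = (g - 2\hat p)/\sqrt{2\hat p(1-\hat p)}$) and averages products over
non-missing variants per pair. Univariate Haseman–Elston regression
regresses $y_iy_j$ on $K_{ij}$ over pairs $i<j$ (diagonal excluded); the
slope is $h^2$ restricted to the variants behind the GRM. The bivariate
form regresses symmetrized cross-products to get the genetic covariance
and $r_g = \mathrm{cov}_g/\sqrt{h^2_1 h^2_2}$, clamped to $[-1,1]$ with
the clamping recorded. Standard errors come from a block jackknife over
subjects (default 100 blocks) — the classic product-regression estimator
with resampling SEs, chosen because the HE implementations used in
practice do not document a single canonical SE formula. Binary traits
enter on the observed 0/1 scale (no liability transform), which the output
flags; estimates are invariant to subject relabeling, and $r_g$ is
symmetric in its arguments. The FDR network applies Benjamini–Hochberg
across all tested pairs and keeps edges with q < 0.05, weighted by signed
$r_g$.

## Haplotype frequencies

Multilocus haplotype frequencies are estimated by the standard EM for
unphased data: the E-step distributes each subject over all haplotype-pair
resolutions of their genotypes, the M-step re-estimates frequencies, and
the log-likelihood is non-decreasing (asserted at every iteration — a
decrease aborts the run as a bug). Genes are inserted progressively in the
given order with pruning at 1e-7 between insertions, so the support stays
restricted to combinations compatible with at least one subject; the full
Cartesian product over eight genes is never materialized. Initialization
is the product of marginal allele frequencies; convergence at
log-likelihood change < 1e-8; output haplotypes below 1e-6 are pruned.
With phase-unambiguous input (all homozygous) the first M-step already
equals direct counting. Only subjects called at every requested gene enter
(excluded subjects are counted in a warning); the conventional five-gene
order A–C–B–DRB1–DQB1 is used for cross-population comparisons.

## QC details

* The Hardy–Weinberg test is the exact conditional test on the
  heterozygote count (no mid-p), matching the default of the standard
  array-QC toolchain; it agrees with a brute-force enumeration oracle to
  1e-12 in the test suite.
* Missing dosages are excluded from MAF/HWE numerators and denominators.
* Relatedness uses the method-of-moments genomic-relationship estimator,
  whose expectation is PI-hat under no inbreeding; pairs above 0.1875
  (halfway between second- and third-degree) drop the lower-call-rate
  member, ties dropping the lexicographically larger ID so the choice is
  deterministic.
* Heterozygosity outliers use genome-wide (here: region-wide, since only
  the MHC is loaded) rates, mean ± 3 SD.
* Coordinates are 1-based and inclusive at both ends throughout.
* The sex-mismatch check runs only when both reported and inferred sex are
  supplied; the package does not infer sex itself (no X-chromosome
  handling).

## The synthetic generator

`simulate_reference_pool()` builds phased haplotypes on a pseudo-chromosome
inside the MHC coordinates: every HLA allele gets a one-hot core SNP
signature near its gene, and a haplotype carrying the allele copies each
signature bit with probability `tagging_strength`, otherwise drawing from
the background frequency. Allele frequencies decrease as $k{:}1$ (four
alleles: 0.40/0.30/0.20/0.10), putting the dominant allele near the
frequencies seen for common HLA alleles in East Asian populations.
Cohorts are random unions of two pool haplotypes, so HWE holds by
construction; phenotypes are additive on the logit (binary; case
fractions around 1–10%) or SD (quantitative; variance fractions well
under 1% at the default effect sizes) scale with sex, age, age² and
standard-normal PCs as covariates. All randomness flows through one
explicit seed.

What the generator does **not** emulate: recombination gradients and
haplotype blocks (LD is signature-mediated, not positional), population
structure beyond injected PCs, genotyping error, rare-allele tails, or
linkage between genes beyond what shared haplotype draws induce. Passing
tests on this generator therefore establishes the *estimators'*
correctness (parameter recovery, calibration, invariances) — not that
real-data accuracy will match the synthetic numbers.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen to finish in
minutes on one CPU while leaving no ambiguity in the pass criteria:
imputation recovery on 2 genes × 4 alleles, tagging 0.95, n = 2,000, 20
classifiers (accuracy ≥ 0.95 required); omnibus null calibration with
5,000 replicates at n = 1,000 (rejection in [0.04, 0.06] at α = 0.05);
HE recovery at n = 2,000 with a 500-variant GRM (h² = 0.3 recovered in
[0.2, 0.4]); conditional recovery at n = 5,000 with planted effects of
0.2 SD per copy. EM tolerances: classifier tables 1e-7, haplotype tables
1e-8, pruning 1e-8/1e-7 as above. Ties are always broken
deterministically (lexicographically) so reruns are bit-identical.

## Known limitations

* Only the eight classical HLA genes have built-in coordinates;
  non-classical genes need user-supplied anchors.
* Six-digit imputation requires three-field training typings; lower-typed
  subjects are an error rather than silently truncated.
* The Firth fallback reports Wald p-values; penalized-likelihood-ratio
  p-values are not implemented.
* HE estimates can leave $[0,1]$ on weak signals; they are reported as
  estimated (h²) or clamped with a record ($r_g$).
* The VCF reader requires biallelic records (split multiallelics
  upstream) and reads the GT field only.
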