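---
title: "Pathway-based GWAS analysis by permutation gene-set enrichment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based GWAS analysis by permutation gene-set enrichment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathgsea)
```

## The problem

Single-marker genome-wide association scans test each SNP in isolation
and only detect loci whose individual effects clear a genome-wide
significance bar. Pathway-based analysis asks a complementary question:
do the genes of a predefined set (a pathway, a GO category) collectively
sit nearer the top of the genome-wide association ranking than chance
allows, even when no single member is genome-wide significant? This
package implements that analysis for a quantitative lipid trait —
plasma triglycerides (TG, mg/dL) — and its threshold-dichotomized
case/control form, together with everything needed to evaluate the
method end to end on synthetic studies: genotype/phenotype simulation,
file I/O, phenotype preparation, single-marker testing, SNP-to-gene
aggregation, two permutation null models, and FDR estimation.

## Phenotype model and preparation

Raw TG is log10-transformed. The base matters only for reporting: every
association statistic used downstream is invariant to a positive
rescaling of the trait, and base 10 makes the plausible mg/dL range
(roughly 34–690) map onto log values of about 1.5–2.8. Preparation then
runs in a fixed order:

1. **Outlier exclusion** — a single pass removes individuals more than
   3 SDs from the mean of log10(TG), with mean and SD computed from all
   values; the rule is deliberately not iterated, so the exclusion set
   is a deterministic function of the input.
2. **BMI adjustment** — ordinary least squares of log10(TG) on BMI over
   the surviving individuals; the residuals are standardized to mean 0,
   SD 1. Standardization makes the adjusted trait invariant to affine
   changes of BMI units. A perfectly collinear fit (zero-SD residuals)
   is a reported error, not a silent zero trait.
3. **Dichotomization** — TG > 200 mg/dL is a case, TG < 150 mg/dL a
   control, and the closed interval [150, 200] is "unknown". Boundary
   values land in the unknown band: the interval assignment is treated
   as the operational rule, and unknown individuals never enter the
   binary analyses or their permutation universe.

## Single-marker testing and quality control

SNPs are filtered before testing: minor-allele frequency must exceed
0.01 and the 1-df Hardy–Weinberg goodness-of-fit P-value must exceed
0.001. Both filters are functions of genotypes alone, so they are
computed once and shared by the observed analysis and every permutation
replicate — labels cannot change QC, and recomputing it B times would
only waste work. The HWE test is computed on all individuals (the
design assumes an unrelated cohort); monomorphic SNPs get P = 1 by
convention.

The quantitative statistic is the 1-df regression F (the squared Wald
t) from `y ~ intercept + dosage`, with P from F(1, n−2). The binary
statistic is the allelic chi-square: a 2×2 case/control ×
counted/other-allele table with two alleles per individual, Pearson
chi-square without continuity correction. The Cochran–Armitage trend
test is available behind `binary_test = "trend"` but is not the
default. Both statistics are invariant to relabeling the counted allele
(dosage → 2 − dosage), which is tested, so the load-time choice of
counted allele (the observed minor allele, ties broken
lexicographically) cannot affect results. P-values are never reported
as exactly zero; exact fits clamp to the smallest positive double and
carry a flag.

## From SNPs to genes to sets

A SNP belongs to a gene when it falls within the gene interval extended
by a 20 kb flank on each side, inclusive at both boundaries (internal
coordinates are 1-based inclusive; BED input is converted at the
boundary). SNPs in overlapping flanked windows count for every
qualifying gene, and strand is ignored — the flank is symmetric in
genomic coordinates. Each gene's representative statistic r(j) is the
maximum over its mapped, QC-surviving SNPs. Genes are ranked by r in
descending order with ties broken by gene id in the C locale, so the
ranking is deterministic across platforms and permutation replicates.

For a set S with N_H members among the N ranked genes, the enrichment
score is the maximum of a weighted Kolmogorov–Smirnov-like running sum:
members at rank j* add |r(j*)|^p / N_R (N_R the sum of |r|^p over
members), non-members subtract 1/(N − N_H), and ES(S) is the maximum of
the partial sums over all N positions. The weight p defaults to 1;
p = 0 recovers the classical unweighted KS statistic. Because the sum
returns exactly to zero at position N and that position participates in
the maximum, ES is non-negative in exact arithmetic; enrichment is
one-sided by construction, which matches the downstream one-sided
empirical P. Two degenerate situations are skipped with a recorded
reason rather than scored: sets with no covered gene (or fewer than
`set_min`, more than `set_max`) and sets covering the entire ranked
list (the miss decrement is undefined). Sets whose covered members all
have zero statistic leave N_R = 0 and are flagged degenerate.

The size filter (default 5–200) applies to *covered* size — members
present among ranked genes — since that is the set size the statistic
actually sees.

## Permutation null models

**Phenotype-label permutation** (the primary mode): each of B
replicates shuffles the phenotype vector across usable individuals —
included, non-missing, and for the binary trait strictly case/control —
while genotype rows stay fixed, then recomputes every SNP statistic,
every gene statistic, the ranking, and every set's ES. This preserves
LD and the gene-size structure exactly, which is the point of the
design: big genes and dense LD inflate r(j) identically in the observed
and permuted worlds.

**SNP-label permutation** (the verification mode): the observed per-SNP
statistic vector — here −log10(P), since this arm consumes a GWAS
P-value file, possibly produced elsewhere — is permuted across SNP
labels with the SNP→gene geometry fixed. This is far cheaper (no
association recomputation) and preserves the multiset of statistics
exactly, but it breaks the correlation between neighbouring SNPs; it is
offered as an independent cross-check of the phenotype-permutation
results, mirroring a two-method verification design. The
significance-proportion correction some i-GSEA implementations apply to
ES is not implemented: the plain ES is used in both modes so that the
two arms differ only in their null model.

For each set, NES = (ES − mean ES_null)/SD(ES_null) using that set's
own null column and the sample SD (n − 1 denominator; the population-SD
alternative would shift all NES by a common factor ~sqrt(B/(B−1)) and
is not offered). The empirical P is (1 + #{ES_null ≥ ES_obs})/(B + 1):
adding one to numerator and denominator makes P attainable at its
resolution 1/(B+1) and never zero; values at the resolution are printed
as `<1/(B+1)` (e.g. `<0.001` at B = 1000). The FDR of a set with
normalized score NES* is the fraction of *all* (set, permutation)
standardized null NES values ≥ NES*, divided by the fraction of
observed sets with NES ≥ NES*. Pooling the standardized nulls across
sets follows the estimator's definition and stabilizes the tail at
moderate B; the comparison uses signed NES exactly as written, the
denominator is at least 1/n_sets by construction, and the reported
value is clipped to [0, 1] with the raw ratio retained.

## The synthetic-study generator

The generator emulates the statistical skeleton of an array-era GWAS
cohort at desk scale. Defaults, chosen once as the package's reference
study conditions:

| parameter | default | why |
|---|---|---|
| individuals | 1000 | cohort-scale sample at desk cost |
| SNPs | 2000 | enough for stable genomic-control estimates |
| genes | 400; sets 50, sizes 5–50 | set-size regime within the 5–200 testing band |
| MAF | Uniform(0.05, 0.5) | common-variant array content |
| log10(TG) | intercept 2.05, residual SD 0.25 | gives ~16% cases (TG > 200) and ~69% controls (TG < 150), resembling an obesity-enriched cohort, and keeps essentially all values inside the 1.53–2.84 post-QC log range |
| BMI | Normal(30, 6), slope 0.005 per kg/m² | wide BMI spread of a case/control obesity sample; a real but minor covariate effect |
| missingness | 1%, completely at random | no missingness model beyond MCAR is assumed |

Genotypes are drawn in Hardy–Weinberg proportions (two Bernoulli(f)
trials), genes are non-overlapping intervals with gaps wide enough that
intergenic SNPs can be placed outside every flanked window, and the
mean SNPs-per-gene is implied by `n_snps`, `intergenic_fraction` and
`n_genes` rather than configured separately (configuring both would
over-determine the design). A designated causal set receives
`n_causal_genes` members each carrying exactly one causal SNP with
additive effect `beta` on log10(TG); `beta_for_target_p()` inverts the
regression power formula so effects can be stated as "per-SNP P ≈
1e-4 at the typical MAF". Optional LD structure copies each causal SNP
into k proxy SNPs whose entries are independently redrawn from HWE with
probability ε, giving expected r² ≈ (1 − ε)²; this exercises the LD
candidate-SNP stage without a coalescent simulator. The generator makes
no attempt to model population structure, relatedness, sex-specific
effects, genotyping error, or realistic genome-wide LD — so passing
calibration and power checks on these studies demonstrates correctness
of the machinery under the stated model, not robustness to confounding
in real cohorts.

Determinism is a contract: one integer seed makes the whole study —
and every analysis run on it — byte-identical, and all analyses first
sort individuals by ID in the C locale so input row order cannot leak
into results or into the permutation stream.

## Numerical choices

* The ES kernel accumulates the running sum sequentially (`cumsum`),
  matching a position-by-position evaluation bit for bit.
* Ranking and every tie-break (`gene_id`, `snp_id`) use radix order,
  independent of the session locale.
* Degenerate SNPs (constant dosage, empty table margins) score 0 with
  P = 1 and a flag rather than erroring a whole scan.
* lambda_GC uses the median chi-square quantile over the null median
  0.4549364; at 2000 SNPs a single study estimates lambda with SE
  ≈ 0.05, so calibration summaries pool SNPs across replicate studies.
* Exact fits (r² within 1e-12 of 1) and perfectly collinear covariates
  are detected by relative tolerance, since floating-point residuals of
  an exact relationship are rounding noise rather than zeros.

## Evaluation sizes

The packaged evaluation (test suite and `scripts/acceptance.R`) uses 20
replicate null studies and 50 replicate causal studies at the default
study conditions with B = 200 permutations, and 200 random instances
for the brute-force ES cross-check. At these sizes the null empirical-P
distribution is uniform to a Kolmogorov–Smirnov distance well under
0.1, pooled lambda_GC sits within 1 ± 0.01, and the causal set is
recovered as the top-ranked set in ≳95% of replicates; the exact
numbers are computed fresh on every run, not stored.

## Known limitations

* Covariates enter by pre-residualization only; there is no
  covariate-in-model regression, logistic regression, or mixed model.
* The binary statistic assumes HWE in the combined sample, as the
  allelic test does.
* SNP-label permutation ignores LD between SNPs, which is precisely why
  it is the verification arm rather than the primary one.
* Multi-mapped SNPs (overlapping flanked windows) contribute to every
  qualifying gene; no deduplication step is applied.
* Gene coordinates are user-supplied and build-agnostic; nothing checks
  them against a genome build.
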