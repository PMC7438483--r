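---
title: "Methods: population differentiation and polygenic burden of type 2 diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population differentiation and polygenic burden of type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model overview

`t2dburden` implements a population-genetic burden analysis for a complex
disease: harmonize an association catalog, quantify how the associated
variants differentiate across populations, test where risk alleles are
enriched or depleted, build a clumped weighted polygenic risk score
(PRS), and estimate its association with prevalent and incident disease.
This vignette records the models, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
conventions adopted where the design was genuinely open.

# Catalog harmonization

An association record carries an effect allele, other allele, odds ratio
(OR), p-value and strand. `harmonize()` applies, in order:

1. significance filter `p_threshold` (default 5e-8, the genome-wide
   convention);
2. reverse-strand records: both alleles complemented, strand set forward.
   Strand-ambiguous pairs (A/T, C/G) on the reverse strand are excluded
   by default because complementing them is a no-op — `keep_ambiguous`
   retains them at the user's risk;
3. OR < 1 records: effect and other allele swapped, OR inverted, so every
   surviving record carries the risk-increasing allele (standard
   harmonization practice; it makes protective-allele reports usable);
4. duplicate SNP ids collapsed keeping the smallest p-value. How
   multi-study duplicates should be merged is not specified anywhere;
   smallest-p retention is our documented choice;
5. risk SNPs are records with harmonized OR ≥ `or_floor` (default 1.2).

Harmonization is idempotent, and complementing twice restores the input —
both are property-tested.

Frequency-spectrum bins follow the common convention with half-open
boundaries: rare < 1% ≤ low-frequency < 5% ≤ common.

# Population differentiation

## Weir–Cockerham Fst

`wc_fst()` implements the 1984 variance-components estimator for two
populations at one biallelic locus using observed heterozygote counts
(genotype-aware, not allele-count-only). With sample sizes $n_1, n_2$,
allele frequencies $p_1, p_2$ and heterozygote proportions $h_1, h_2$:

$$\theta = \frac{a}{a + b + c}$$

where $a$, $b$, $c$ are the among-population, among-individual-within-
population and within-individual components. $\theta$ may be negative
(finite-sample estimator); it is undefined when the denominator is zero
(both populations monomorphic for the same allele) or a population has
fewer than two genotyped individuals — flagged, never a crash. The
per-pair summary reported as primary is the arithmetic mean of defined
per-SNP estimates ("mean Fst"); the ratio-of-sums estimator
$\sum a / \sum(a+b+c)$ is carried as a secondary field because it is the
better-behaved average for genome-wide summaries.

## Frequency-matched random-SNP null

To ask whether trait-associated SNPs are unusually differentiated,
`sample_frequency_matched()` draws, for each target SNP, one background
SNP without replacement from the same allele-frequency bin (default width
0.02). Matching uses the pooled minor-allele frequency: Fst is
allele-symmetric, so the folded frequency is the right matching scale.
Exhausted bins fall back to the nearest non-empty bin with a warning. A
property test verifies the matched set's per-bin histogram equals the
target's exactly when the pool suffices, and that the Kolmogorov–Smirnov
distance between the two frequency distributions is below the bin width.

## High-Fst selection test

A SNP's summary differentiation is the maximum of its pairwise $\theta$
values. "High-Fst" is a conjunction: summary > `fst_floor` (default 0.05)
AND above the (1 − `top_quantile`) quantile (default top 1%) of the
pooled summary distribution of both sets. "Top 1% across all
populations" admits several readings (per-pair vs pooled); the pooled
convention is ours and is stated here. Counts are compared by Pearson
chi-square on the 2×2 table, no continuity correction, 1 df, upper tail —
the simplest test consistent with a printed p ≈ 0.67 at a statistic of
0.178. The reference analysis's printed statistic is not reproducible
from its printed counts by any standard 2×2 test we coded; the package
implements the standard test and records the discrepancy rather than
reverse-engineering the original calculation.

## Genotype PCA

Dosages are mean-imputed per SNP, centered at $2\hat p$ and scaled by
$\sqrt{2\hat p(1-\hat p)}$ (the usual genotype standardization);
monomorphic SNPs are dropped; scores come from an eigendecomposition of
the smaller Gram matrix, which is algebraically the SVD of the
standardized matrix. Score columns are mutually orthogonal (tested at
1e-8) and duplicated samples receive identical scores.

# Enrichment analysis

For each risk SNP and population, the 2×2 table compares risk/non-risk
allele counts (2N-based, not genotype counts) in the population against
the pooled global population. Two deliberate conventions:

* the global pool **includes** the tested population. This induces a
  positive dependence between the margins; it is noted, not corrected,
  and `leave_one_out = TRUE` offers the alternative pool;
* BH-FDR is applied **within population** across SNPs, because
  significance is reported per population; `fdr_scope = "global"` pools
  all tests instead.

The two-sided Fisher p-value sums hypergeometric probabilities of tables
no more probable than the observed one, with the classical relative
tolerance 1e-7 on the "no more probable" comparison. Significance is
strict (q < alpha exactly at the boundary is *not* significant). Signed
heatmap scores are $-\log_{10} q$ for enrichment and $+\log_{10} q$
(negative) for depletion; q-values are floored at 1e-300 so extreme
counts cannot produce infinities. Heatmap rows are ordered by
agglomerative clustering (Euclidean distance, complete linkage) and the
two-cluster cut is reported, mirroring the two discrete
enrichment/depletion patterns the analysis is designed to surface.

# Polygenic risk score

Greedy clumping visits SNPs in ascending p-value (ties by position, then
id); an index SNP removes not-yet-visited SNPs within ±`window_bp`
(default 250,000 bp) on the same chromosome with squared Pearson dosage
correlation above `r2_threshold` (default 0.1). Composite (genotypic) LD
needs no phasing. Post-hoc assertions verify no retained pair violates
the threshold within the window.

The score is the raw weighted sum $\sum_j \ln(\mathrm{OR}_j) d_{ij}$:
log-odds weighting is the convention of standard scoring software and
preserves additivity over disjoint SNP sets (property-tested). Missing
dosages are mean-imputed at twice the cohort effect-allele frequency.
Only rank matters downstream, so no per-allele averaging is applied.
Quintiles use the linear-interpolation (type 7) empirical percentiles at
20/40/60/80; boundary ties go to the lower quintile; categories are
low = Q1, moderate = Q2–4, high = Q5 (the quintile-to-category mapping is
not printed anywhere; this is our documented convention). By default the
pipeline scores the SNPs significantly *enriched* in the target
population, with `score_snps = "all_risk"` as the alternative; discovery
ORs are taken from the catalog as-is.

# Association models

* **Prevalence**: log-link Poisson fit of prevalent status on quintile
  indicators + age, sex, BMI, with HC0 sandwich standard errors (the
  modified-Poisson approach for common binary outcomes; "robust" alone
  does not pin the form, HC0 is our choice). No person-time offset: the
  estimand is a prevalence ratio on baseline status.
* **Incidence**: Cox proportional hazards with Efron tie handling (the
  less-biased default), on the prevalent-free subcohort; both the
  age/sex/BMI model and the full model with six additional biomarkers.
  Quintiles with zero events are flagged non-identifiable rather than
  reported.
* **Cumulative incidence**: 1 − Kaplan–Meier per risk category.
* **Biomarkers**: OLS of each biomarker on quintile indicators + age,
  sex, BMI and the other five biomarkers, prevalent-free subcohort.

All intervals are Wald ±1.96 SE on the log (PR, HR) or identity (beta)
scale; no bootstrap.

# The synthetic world

The generator exists so that every stage has a testable stated world. It
emulates:

* **Population structure** via the Balding–Nichols model: population
  frequency ~ Beta$(p(1-c)/c,\,(1-p)(1-c)/c)$ around ancestral $p$, with
  divergence $c$ per population. Defaults (AFR 0.15, EAS 0.12, AMR 0.05,
  SAS 0.025, EUR/IR 0.02; panel sizes 661/504/347/489/503/842) reproduce
  the observed *ordering* of pairwise differentiation: the target
  population nearest EUR/SAS, farthest from AFR/EAS. A pilot froze the
  realized mapping: mean pairwise Weir–Cockerham Fst between two
  populations of equal $c$ ≈ $0.47 \cdot 2c/(1+c)$, regression-tested at
  25% relative tolerance.
* **LD** as independent blocks (default 5 SNPs): within a block every SNP
  copies a shared latent uniform with probability $w$ and draws fresh
  otherwise, so any two block SNPs correlate at $w^2$ and
  $w = \mathrm{ld\_r2}^{1/4}$ gives pairwise dosage $r^2 \approx$
  `ld_r2` (default 0.9). Ancestral frequency and the Balding–Nichols draw
  are shared within a block so the target is interpretable. This is
  enough to exercise clumping; there is no recombination map.
* **The catalog**: `n_catalog_snps` (default 2,302) of `n_snps` (default
  5,000) variants get association records; the remainder is the
  background pool for frequency-matched sampling. 212 risk SNPs with OR
  in [1.2, 1.5]; 15% of records are reported on the reverse strand and
  20% with the protective allele as effect allele (both fractions
  invented) to exercise harmonization.
* **Phenotypes**: the true score is the weighted dosage sum,
  standardized. Prevalent status is Bernoulli with a **log link**,
  $P = \exp(\alpha + \beta_\mathrm{prev} s + 0.2 z_\mathrm{age} +
  0.15 z_\mathrm{BMI})$, capped at 0.95, with $\alpha$ calibrated so the
  mean prevalence hits `target_prevalence` (default 0.4, the motivating
  cohort's case fraction). The log link makes `prevalence_beta` an exact
  log prevalence-ratio per score SD — the quantity the recovery tests
  target; a logistic link would only approximate it. A consequence worth
  stating: because the intercept is recalibrated, the *mean* prevalence
  is flat in `prevalence_beta`; monotonicity is tested as non-decrease
  within noise. Incident times are exponential with rate
  $\lambda_0 \exp(\beta_\mathrm{haz} s + 0.15 z_\mathrm{age} +
  0.1 z_\mathrm{BMI})$ ($\lambda_0$ = 0.02/person-year), censored by
  drop-out (0.02/year) and administratively at 18 years (a cohort
  followed ~1999–2017); prevalent cases carry no follow-up. Covariates
  and biomarkers are drawn at typical adult cohort scales; fasting and
  2-h glucose are shifted up for prevalent cases, mirroring a
  glucose-based case definition.
* **Effect calibration**: the normal-theory mapping
  $\beta = \log(\mathrm{ratio})/2.8016$ (2.8016 = distance between the
  top and bottom quintile means of a standard normal) is the default;
  `calibrate_quintile_effect()` solves
  $E[e^{\beta s}\mid Q5]/E[e^{\beta s}\mid Q1] = \mathrm{target}$ on the
  realized score distribution, making the true quintile contrast exact
  per simulated world. Recovery tests average the log estimate over
  replicate cohorts because the Cox sampling SE of a quintile contrast at
  n = 10,000 (~0.08 on the log scale) is material relative to the
  acceptance band; a large-n check shows the Cox estimand itself sits
  slightly below the time-zero ratio (frailty attenuation of a
  misspecified group-indicator model), about 1.97 for a true 2.0.

It does **not** emulate: demographic history, selection, recombination
maps, genotyping or imputation error, age structure correlated with
genotype, competing risks, or informative censoring. A green test
therefore establishes correctness of the estimators on their stated
models — not robustness to the ways real cohort data violate them.

All randomness flows from one master seed through named substreams
(frequencies, variants, genotypes per population, gwas, phenotypes), so
a stage can be regenerated without replaying the stream; fixed seed gives
byte-identical VCF and phenotype files (tested).

# Numerical conventions and degenerate inputs

* Fisher's two-sided p: relative tolerance 1e-7 when comparing table
  probabilities; p capped at 1.
* Fst: undefined flags propagate (never NaN crashes); oracle equivalence
  is asserted at absolute 1e-12 — θ is bounded by 1 and can sit near 0,
  where relative tolerance between two evaluation orders of the same
  formula is meaningless.
* Fold differences: no pseudo-counts; x/0 flagged infinite, 0/0 undefined
  and excluded from maxima.
* Quintiles require ≥ 5 distinct score values; an all-equal score vector
  is a documented error, not a silent single quintile.
* The pipeline refuses to run a stage whose upstream outputs are missing,
  naming the stage to run; the manifest records parameters, seed, package
  version and MD5 checksums of every written file, and reruns are
  checksum-identical.

# Known limitations

* The pooled-global enrichment test double-counts the tested population's
  alleles (by design, matching the reference analysis); leave-one-out
  pooling is available but off by default.
* The robust Poisson model can predict probabilities above 1 for extreme
  covariate patterns; the simulator caps true probabilities at 0.95, and
  the estimator inherits the usual log-link caveat.
* Clumping r² comes from the target-population reference panel itself; no
  external LD reference is supported.
* PRSice-style p-value-threshold optimization and cross-ancestry weight
  adjustment are out of scope.
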