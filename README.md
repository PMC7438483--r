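# t2dburden

Population differentiation and polygenic burden analysis for type 2
diabetes (T2D), as an installable, tested R pipeline.

Complex-disease risk alleles are unevenly distributed across human
populations. Given (a) multi-population genotypes (VCF + sample panel),
(b) a GWAS association catalog (variant, effect allele, odds ratio,
p-value, strand, gene) and (c) longitudinal phenotypes for one target
cohort, the package answers three questions:

1. **How differentiated are the disease-associated variants?**
   Per-population effect-allele frequencies, per-SNP pairwise
   Weir–Cockerham Fst, a high-Fst "selection" test against a
   frequency-matched random-SNP null, and genotype PCA.
2. **Where are risk alleles enriched or depleted?** Per SNP and
   population, Fisher's exact test of risk-allele counts against the
   pooled global population, Benjamini–Hochberg FDR within population,
   gene-level rankings, and a signed −log10(q) heatmap matrix with a
   two-cluster cut.
3. **Does the resulting polygenic score predict disease?** Greedy LD
   clumping (r² > 0.1 within 250 kb), a log-odds-weighted polygenic risk
   score, score quintiles and low/moderate/high risk categories, then
   prevalence ratios (robust Poisson, HC0 sandwich), hazard ratios (Cox,
   Efron ties), cumulative incidence (1 − Kaplan–Meier) and biomarker
   regressions.

Because the motivating cohort data are not public, the package ships a
first-class simulator: Balding–Nichols population frequencies
(freq ~ Beta(p(1−c)/c, (1−p)(1−c)/c)), block-diagonal LD with a
calibrated within-block r² target, a GWAS summary table with planted
reverse-strand and protective-allele records, and phenotypes from a
log-link prevalence model plus an exponential proportional-hazards
incidence model, both driven by the true score. Every downstream stage is
tested against this stated world and against independent oracles.

## Core statistics

* **Weir–Cockerham Fst** (two populations, one locus): variance
  components a (among populations), b (among individuals), c (within
  individuals) from sample sizes, allele frequencies and observed
  heterozygosity; θ = a/(a+b+c), undefined when both populations are
  monomorphic for the same allele.
* **Enrichment**: 2×2 allele-count table [risk, non-risk] in the
  population vs the pooled global population (which includes the tested
  population); two-sided Fisher p; BH q within population; significant
  means q < 0.05 strictly; signed score = −log10(q) for enrichment,
  +log10(q) for depletion.
* **PRS**: score_i = Σ_j ln(OR_j) · dosage_ij over clumped index SNPs,
  missing dosages imputed at twice the cohort effect-allele frequency;
  quintiles at the empirical 20/40/60/80 percentiles.

## Worked example

```r
library(t2dburden)

pops <- list(population_spec("AFR", 150, 0.15), population_spec("AMR", 150, 0.05),
             population_spec("EAS", 150, 0.12), population_spec("EUR", 150, 0.02),
             population_spec("IR", 1500, 0.02), population_spec("SAS", 150, 0.025))
cfg <- sim_config(n_snps = 1000, n_catalog_snps = 500, n_risk_snps = 120,
                  populations = pops, seed = 42)
sim <- simulate_dataset(cfg)

cat_h <- harmonize(sim$gwas)
#> harmonized_catalog: 500 records (120 risk SNPs, OR >= 1.20), 0 excluded

f <- fst_pairwise(sim$genotypes, snp_ids = cat_h$records$snp_id,
                  pairs = cbind(rep("IR", 5), c("AFR","AMR","EAS","EUR","SAS")))
aggregate(theta ~ pop_b, data = f[!f$undefined, ], FUN = mean)
#>   pop_b      theta
#> 1   AFR 0.07955495
#> 2   AMR 0.03633319
#> 3   EAS 0.06414396
#> 4   EUR 0.02157689
#> 5   SAS 0.02498178
```

The target population is closest to EUR/SAS and most differentiated from
AFR/EAS — the ordering the simulator's divergence parameters encode.

```r
fr  <- allele_frequencies(sim$genotypes, cat_h)
enr <- test_enrichment(cat_h, fr)
ir  <- subset_genotypes(sim$genotypes, samples =
         sim$genotypes$panel$sample_id[sim$genotypes$panel$population == "IR"])
keep <- unique(enr$snp_id[enr$population == "IR" & enr$significant &
                          enr$direction == "enriched"])        # 31 SNPs
risk <- cat_h$risk_subset[cat_h$risk_subset$snp_id %in% keep, ]
idx  <- ld_clump(risk, ir, clump_config())                     # 23 index SNPs
prs  <- compute_prs(ir, risk[risk$snp_id %in% idx, ])
cohort <- build_cohort(sim$phenotypes, prs)
prevalence_ratios(cohort)[, c("contrast", "estimate", "ci_low", "ci_high", "pvalue")]
#>  contrast  estimate    ci_low  ci_high       pvalue
#>  Q2 vs Q1 0.9128012 0.7369208 1.130659 0.4034460126
#>  Q3 vs Q1 1.0213419 0.8298363 1.257042 0.8420035963
#>  Q4 vs Q1 1.1956292 0.9830486 1.454180 0.0736419304
#>  Q5 vs Q1 1.3961437 1.1611812 1.678650 0.0003860344
```

Prevalent disease rises with score quintile and is significantly elevated
in the top quintile (PR 1.40, 95% CI 1.16–1.68): the 31 enriched risk
SNPs capture part of the full 120-SNP generative signal, so the gradient
is attenuated relative to the true top-vs-bottom prevalence ratio of 1.5.
`hazard_ratios(cohort)` gives the incident-disease analogue (Cox; at this
cohort size its quintile CIs are wide), and
`cumulative_incidence(cohort)` the 1 − Kaplan–Meier curves per risk
category.

The whole chain is also available as one call over files on disk:

```r
simulate_dataset(cfg, out_dir = "run/input")
rc <- run_config(vcf = "run/input/genotypes.vcf", panel = "run/input/panel.tsv",
                 gwas = "run/input/gwas_summary.tsv",
                 phenotypes = "run/input/phenotypes.csv", out_dir = "run/output")
run_pipeline(rc, stages = "all")   # writes TSV/JSON outputs + manifest.json
```

or from a shell:
`Rscript -e 't2dburden::pipeline_cli()' simulate --dir run && Rscript -e 't2dburden::pipeline_cli()' run-all --dir run`.

## Layout

* `R/synthetic_data.R` — population/LD/phenotype simulator and writers
* `R/snp_catalog.R` — GWAS-table harmonization, frequency spectrum
* `R/popfreq.R` — per-population allele frequencies, fold differences
* `R/differentiation.R` — Weir–Cockerham Fst, matched null, chi-square
  selection test, genotype PCA
* `R/enrichment.R` — Fisher/BH enrichment, gene counts, heatmap matrix
* `R/prs.R` — LD clumping, PRS, quintiles
* `R/association.R` — robust Poisson, Cox, Kaplan–Meier, biomarker OLS
* `R/pipeline.R` — staged pipeline, manifest, CLI
* `vignettes/methods.Rmd` — models, assumptions, calibration choices
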