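Package: t2dburden
Title: Population Differentiation and Polygenic Burden Analysis for Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Burden", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying the population-genetic burden of
    type 2 diabetes from multi-population genotype data. Harmonizes GWAS
    association tables (strand orientation, effect-allele flipping, risk-allele
    definition), computes per-population effect-allele frequencies, per-SNP
    Weir-Cockerham Fst with a frequency-matched random-SNP null and genotype
    PCA, tests per-population risk-allele enrichment and depletion against a
    pooled global population with Fisher's exact test and Benjamini-Hochberg
    FDR, LD-clumps risk SNPs and computes a log-odds-weighted polygenic risk
    score, and estimates the association of score quintiles with prevalent
    disease (robust Poisson prevalence ratios), incident disease (Cox hazard
    ratios, cumulative incidence) and quantitative biomarkers. Includes a
    Balding-Nichols simulator of multi-population genotypes, summary
    statistics and phenotypes so every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
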