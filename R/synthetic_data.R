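#' Population specification for the genotype simulator
#'
#' @param name population label (e.g. "AFR", "IR").
#' @param n_samples number of diploid individuals, >= 1.
#' @param fst_to_ancestral Balding-Nichols divergence parameter c in [0, 1):
#'   the drift of this population away from the shared ancestral allele
#'   frequencies. c = 0 means no divergence.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(name, n_samples, fst_to_ancestral) {
  if (!is.numeric(n_samples) || n_samples < 1)
    stop("n_samples must be >= 1")
  if (!is.numeric(fst_to_ancestral) || fst_to_ancestral < 0 || fst_to_ancestral >= 1)
    stop("fst_to_ancestral must be in [0, 1)")
  structure(list(name = as.character(name), n_samples = as.integer(n_samples),
                 fst_to_ancestral = fst_to_ancestral),
            class = "population_spec")
}

#' Default six-population panel
#'
#' Sample sizes follow the six analysis panels (five 1000-Genomes-style
#' super-populations plus the whole-genome-sequenced target cohort);
#' divergence parameters place the target population close to EUR/SAS and
#' far from AFR/EAS, reproducing the observed ordering of pairwise
#' differentiation.
#'
#' @return list of [population_spec()] objects (AFR, AMR, EAS, EUR, IR, SAS).
#' @export
default_populations <- function() {
  # Sample sizes follow the six analysis panels (five 1000-Genomes
  # super-populations plus the WGS target cohort); divergence parameters are
  # chosen so the target population sits close to EUR/SAS and far from
  # AFR/EAS, reproducing the observed ordering of pairwise differentiation.
  list(
    population_spec("AFR", 661, 0.15),
    population_spec("AMR", 347, 0.05),
    population_spec("EAS", 504, 0.12),
    population_spec("EUR", 503, 0.02),
    population_spec("IR",  842, 0.02),
    population_spec("SAS", 489, 0.025))
}

#' Simulation configuration
#'
#' Captures the whole stated world of the generator: catalog size, allele
#' frequency spectrum, population panel, linkage-disequilibrium structure,
#' effect sizes, and the phenotype models. Defaults mirror the scale of the
#' study design the package emulates: a 2,302-SNP association catalog with
#' 212 risk SNPs (odds ratio >= 1.2), six populations, and a prospective
#' cohort followed ~18 years with roughly 40% prevalent disease at baseline
#' and ~2 incident events per 100 person-years at the mean score.
#'
#' @param n_snps total number of simulated variants (the catalog SNPs plus
#'   a background pool used for frequency-matched random-SNP sampling).
#' @param n_catalog_snps number of variants carried in the association
#'   catalog (must be <= n_snps).
#' @param ancestral_freq_range interval in (0,1) for ancestral allele
#'   frequencies (drawn uniformly).
#' @param populations list of [population_spec()] objects.
#' @param ld_block_size variants per correlated block (1 = no LD).
#' @param ld_r2 target pairwise squared dosage correlation within a block.
#' @param n_risk_snps number of variants given odds ratio in `or_range`.
#' @param or_range odds-ratio interval for risk variants; lower bound >= 1.2.
#' @param prevalence_beta log prevalence-ratio per standard deviation of the
#'   true polygenic score (log-link prevalence model).
#' @param hazard_beta log hazard-ratio per standard deviation of the true
#'   polygenic score.
#' @param baseline_hazard events per person-year at the mean score.
#' @param censoring_rate per-year random drop-out rate (0 = administrative
#'   censoring only).
#' @param followup_years administrative censoring horizon in years.
#' @param target_prevalence mean baseline disease prevalence.
#' @param missing_rate fraction of dosages set missing (exercises the
#'   missing-data rules downstream).
#' @param seed master seed; all stage substreams derive from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 5000,
                       n_catalog_snps = 2302,
                       ancestral_freq_range = c(0.05, 0.95),
                       populations = default_populations(),
                       ld_block_size = 5,
                       ld_r2 = 0.9,
                       n_risk_snps = 212,
                       or_range = c(1.2, 1.5),
                       prevalence_beta = log(1.5) / 2.8016,
                       hazard_beta = log(2) / 2.8016,
                       baseline_hazard = 0.02,
                       censoring_rate = 0.02,
                       followup_years = 18,
                       target_prevalence = 0.4,
                       missing_rate = 0,
                       seed = 1L) {
  if (n_catalog_snps > n_snps) stop("n_catalog_snps must be <= n_snps")
  if (n_risk_snps > n_catalog_snps) stop("n_risk_snps must be <= n_catalog_snps")
  if (or_range[1] < 1.2) stop("or_range lower bound must be >= 1.2 for risk variants")
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (ld_r2 <= 0 || ld_r2 > 1) stop("ld_r2 must be in (0, 1]")
  stopifnot(all(vapply(populations, inherits, TRUE, "population_spec")))
  structure(list(
    n_snps = as.integer(n_snps), n_catalog_snps = as.integer(n_catalog_snps),
    ancestral_freq_range = ancestral_freq_range,
    populations = populations, ld_block_size = as.integer(ld_block_size),
    ld_r2 = ld_r2, n_risk_snps = as.integer(n_risk_snps), or_range = or_range,
    prevalence_beta = prevalence_beta, hazard_beta = hazard_beta,
    baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
    followup_years = followup_years, target_prevalence = target_prevalence,
    missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config")
}

#' Balding-Nichols population allele frequencies
#'
#' Draws per-population frequencies around the ancestral frequencies: at
#' divergence c, the frequency at a SNP with ancestral frequency p is drawn
#' from Beta(p(1-c)/c, (1-p)(1-c)/c), which has mean p and variance
#' c p(1-p). c = 0 returns the ancestral frequencies unchanged.
#'
#' @param ancestral_freqs numeric vector of ancestral frequencies in (0,1);
#'   values outside are clipped into [0,1] first.
#' @param spec a [population_spec()].
#' @param seed integer seed for this draw.
#' @return numeric vector of population frequencies, clipped to [0,1].
#' @export
simulate_population_frequencies <- function(ancestral_freqs, spec, seed) {
  stopifnot(inherits(spec, "population_spec"))
  c_par <- spec$fst_to_ancestral
  p <- pmin(pmax(ancestral_freqs, 0), 1)
  if (c_par == 0) return(p)
  with_seed(seed, {
    k <- (1 - c_par) / c_par
    q <- stats::rbeta(length(p), pmax(p * k, 1e-12), pmax((1 - p) * k, 1e-12))
    pmin(pmax(q, 0), 1)
  })
}

block_index <- function(n_snps, block_size) {
  ((seq_len(n_snps) - 1L) %/% block_size) + 1L
}

variant_table <- function(n_snps, block_size, seed) {
  # contiguous 10-kb spacing; chromosome chunks aligned to whole LD blocks
  chunk <- max(block_size, ceiling(n_snps / 22 / block_size) * block_size)
  idx <- seq_len(n_snps) - 1L
  chrom <- as.character((idx %/% chunk) + 1L)
  pos <- (idx %% chunk) * 10000L + 1L
  pairs <- rbind(c("A", "G"), c("A", "C"), c("C", "T"), c("G", "T"),
                 c("A", "T"), c("C", "G"))
  al <- with_seed(seed, pairs[sample.int(6, n_snps, replace = TRUE), , drop = FALSE])
  data.frame(snp_id = sprintf("rs%06d", seq_len(n_snps)),
             chrom = chrom, pos = pos,
             ref = al[, 1], alt = al[, 2], stringsAsFactors = FALSE)
}

#' Simulate per-population frequencies for a whole configuration
#'
#' Ancestral frequencies are drawn uniformly on the configured range, shared
#' within each LD block (so the within-block correlation target is
#' interpretable), and then diverged per population with
#' [simulate_population_frequencies()]; the Balding-Nichols draw is also
#' shared within a block.
#'
#' @param config a [sim_config()].
#' @return list with `ancestral` (length n_snps) and `pop_freqs`
#'   (n_snps x n_populations matrix, columns named by population).
#' @export
simulate_frequency_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  blocks <- block_index(config$n_snps, config$ld_block_size)
  n_blocks <- max(blocks)
  anc_block <- with_seed(substream_seed(config$seed, "frequencies"),
                         stats::runif(n_blocks, config$ancestral_freq_range[1],
                                      config$ancestral_freq_range[2]))
  ancestral <- anc_block[blocks]
  pop_freqs <- vapply(seq_along(config$populations), function(i) {
    sp <- config$populations[[i]]
    fb <- simulate_population_frequencies(
      anc_block, sp, substream_seed(config$seed, paste0("frequencies.", sp$name)))
    fb[blocks]
  }, numeric(config$n_snps))
  colnames(pop_freqs) <- vapply(config$populations, `[[`, "", "name")
  list(ancestral = ancestral, pop_freqs = pop_freqs)
}

simulate_haplotypes <- function(n_hap, freqs, blocks, ld_r2) {
  # Within a block every SNP copies a shared latent uniform with probability
  # w and is drawn independently otherwise; any two block SNPs then share
  # the latent with probability w^2, giving allele correlation w^2 and
  # squared correlation w^4 = ld_r2 when frequencies are equal in the block.
  n_snp <- length(freqs)
  w <- ld_r2^(1 / 4)
  H <- matrix(0L, n_hap, n_snp)
  for (b in unique(blocks)) {
    js <- which(blocks == b)
    if (length(js) == 1L || ld_r2 == 0) {
      for (j in js) H[, j] <- as.integer(stats::runif(n_hap) < freqs[j])
      next
    }
    u_shared <- stats::runif(n_hap)
    for (j in js) {
      use_shared <- stats::runif(n_hap) < w
      u <- ifelse(use_shared, u_shared, stats::runif(n_hap))
      H[, j] <- as.integer(u < freqs[j])
    }
  }
  H
}

#' Simulate genotypes for all populations
#'
#' Within a population, per-SNP dosages are Binomial(2, freq) draws except
#' inside LD blocks, where a shared latent haplotype construction yields
#' pairwise squared dosage correlation close to the `ld_r2` target.
#'
#' @param pop_freqs n_snps x n_populations frequency matrix (as produced by
#'   [simulate_frequency_table()]), values in [0,1].
#' @param config a [sim_config()] (population sizes, LD structure, missing
#'   rate and master seed are taken from it).
#' @return a [genotype_matrix()] covering all populations.
#' @export
simulate_genotypes <- function(pop_freqs, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(pop_freqs < 0 | pop_freqs > 1)) stop("frequencies must be in [0,1]")
  n_total <- sum(vapply(config$populations, `[[`, 1L, "n_samples"))
  if (n_total == 0) stop("zero samples")
  n_snps <- nrow(pop_freqs)
  blocks <- block_index(n_snps, config$ld_block_size)
  variants <- variant_table(n_snps, config$ld_block_size,
                            substream_seed(config$seed, "variants"))
  dos <- matrix(NA_real_, n_total, n_snps)
  sample_ids <- character(n_total)
  pops <- character(n_total)
  row0 <- 0L
  for (sp in config$populations) {
    f <- pop_freqs[, sp$name]
    d <- with_seed(substream_seed(config$seed, paste0("genotypes.", sp$name)), {
      h1 <- simulate_haplotypes(sp$n_samples, f, blocks, config$ld_r2)
      h2 <- simulate_haplotypes(sp$n_samples, f, blocks, config$ld_r2)
      h1 + h2
    })
    idx <- row0 + seq_len(sp$n_samples)
    dos[idx, ] <- d
    sample_ids[idx] <- sprintf("%s_%04d", sp$name, seq_len(sp$n_samples))
    pops[idx] <- sp$name
    row0 <- row0 + sp$n_samples
  }
  if (config$missing_rate > 0) {
    dos <- with_seed(substream_seed(config$seed, "missing"), {
      drop <- matrix(stats::runif(length(dos)) < config$missing_rate,
                     nrow(dos), ncol(dos))
      dos[drop] <- NA_real_
      dos
    })
  }
  rownames(dos) <- sample_ids
  genotype_matrix(dos, variants,
                  data.frame(sample_id = sample_ids, population = pops,
                             stringsAsFactors = FALSE))
}

#' Simulate a GWAS association summary table
#'
#' Produces one association record for each of `n_catalog_snps` variants
#' sampled from the simulated panel (the remaining variants form the
#' background pool for frequency-matched random-SNP sampling):
#' `n_risk_snps` of them get odds ratios in `or_range` (risk variants,
#' OR >= 1.2), the rest get odds ratios in (1/1.19, 1.19) so they fall
#' below the risk
#' threshold after orientation. A fraction of records is reported on the
#' reverse strand and a fraction with the protective allele as effect
#' allele (OR < 1), exercising the harmonization rules downstream. Risk
#' variants are annotated with gene symbols weighted toward a handful of
#' canonical diabetes genes.
#'
#' @param variants variant metadata data.frame (from a [genotype_matrix()]).
#' @param config a [sim_config()].
#' @param reverse_frac fraction of records reported on the reverse strand.
#' @param protective_frac fraction of records reported with OR < 1.
#' @return data.frame with columns snp_id, chr, pos, effect_allele,
#'   other_allele, or, pvalue, strand, gene (one row per catalog SNP);
#'   attribute `risk_weights` holds the true log odds ratios (0 for
#'   non-risk and non-catalog variants) aligned to the FULL simulated
#'   variant order.
#' @export
simulate_gwas_table <- function(variants, config, reverse_frac = 0.15,
                                protective_frac = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  n_all <- nrow(variants)
  with_seed(substream_seed(config$seed, "gwas"), {
    cat_idx <- sort(sample.int(n_all, min(config$n_catalog_snps, n_all)))
    n <- length(cat_idx)
    risk_pos <- sort(sample.int(n, config$n_risk_snps))
    risk_idx <- cat_idx[risk_pos]
    or <- exp(stats::runif(n, log(1.005), log(1.19)))
    or[risk_pos] <- exp(stats::runif(config$n_risk_snps,
                                     log(config$or_range[1]),
                                     log(config$or_range[2])))
    pval <- 10^stats::runif(n, -30, log10(5e-8))
    variants <- variants[cat_idx, , drop = FALSE]
    genes <- c("TCF7L2", "CDKAL1", "IGF2BP2", "SLC16A11", "CDKN1C",
               "SLC16A13", "CDKN2B", "HLA-DQA2", "TECRL", "KCNJ11",
               "PPARG", "HHEX", "FTO", "IGF2", "WFS1")
    gene <- rep("", n)
    gene[risk_pos] <- sample(genes, config$n_risk_snps, replace = TRUE,
                             prob = c(0.3, 0.15, 0.12, 0.08, 0.05,
                                      rep(0.03, 10)))
    # true generative weights, aligned to the FULL variant order
    weights <- rep(0, n_all)
    weights[risk_idx] <- log(or[risk_pos])
    eff <- variants$alt
    oth <- variants$ref
    # report some records protective-side (effect/other swapped, OR inverted)
    flip <- stats::runif(n) < protective_frac
    tmp <- eff[flip]; eff[flip] <- oth[flip]; oth[flip] <- tmp
    or[flip] <- 1 / or[flip]
    # report some records on the reverse strand (alleles complemented),
    # avoiding strand-ambiguous pairs for which the complement is a no-op
    ambig <- is_strand_ambiguous(eff, oth)
    rev <- stats::runif(n) < reverse_frac & !ambig
    eff[rev] <- complement_allele(eff[rev])
    oth[rev] <- complement_allele(oth[rev])
    out <- data.frame(
      snp_id = variants$snp_id, chr = variants$chrom, pos = variants$pos,
      effect_allele = eff, other_allele = oth, or = or, pvalue = pval,
      strand = ifelse(rev, "reverse", "forward"), gene = gene,
      stringsAsFactors = FALSE)
    attr(out, "risk_weights") <- weights
    out
  })
}

#' Simulate baseline covariates, prevalent status and incident outcomes
#'
#' The true polygenic score s_i = sum_j w_j dosage_ij is standardized.
#' Prevalent disease follows a log-link (relative-risk) model,
#' P(prevalent) = exp(alpha + prevalence_beta * s + covariate terms), with
#' alpha calibrated to the configured mean prevalence, so `prevalence_beta`
#' is an exact log prevalence-ratio per score SD. Non-prevalent individuals
#' get an exponential event time with rate
#' baseline_hazard * exp(hazard_beta * s + covariate terms), censored by
#' random drop-out (`censoring_rate` per year) and administratively at
#' `followup_years`. Covariates (age, sex, BMI, six biomarkers) are drawn
#' at typical adult cohort scales; fasting and 2-h glucose are shifted
#' upward for prevalent cases, mirroring a glucose-based case definition.
#'
#' @param genotypes a [genotype_matrix()] for the cohort.
#' @param weights per-SNP log odds ratio vector aligned to the genotype
#'   variants (length must match).
#' @param config a [sim_config()].
#' @return data.frame (class `cohort_table`) with columns sample_id, sex,
#'   age, bmi, fpg, g2h, tc, tg, hdl, ldl, prevalent_t2d, time_years,
#'   event, plus the true standardized score in `true_score`.
#' @export
simulate_phenotypes <- function(genotypes, weights, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "sim_config"))
  if (length(weights) != ncol(genotypes$dosages))
    stop("weights must align with genotype variants (length mismatch)")
  dos <- genotypes$dosages
  dos[is.na(dos)] <- 0
  s <- as.numeric(dos %*% weights)
  if (stats::sd(s) > 0) s <- (s - mean(s)) / stats::sd(s) else s <- s - mean(s)
  n <- nrow(dos)
  with_seed(substream_seed(config$seed, "phenotypes"), {
    sex <- stats::rbinom(n, 1, 0.5)
    age <- pmin(pmax(stats::rnorm(n, 45, 12), 20), 80)
    bmi <- pmax(stats::rnorm(n, 27, 4.5), 15)
    z_age <- (age - 45) / 12
    z_bmi <- (bmi - 27) / 4.5
    fpg <- stats::rnorm(n, 88, 8)
    g2h <- stats::rnorm(n, 100, 25)
    tc  <- stats::rnorm(n, 200, 44)
    tg  <- pmax(stats::rnorm(n, 150, 80), 30)
    hdl <- pmax(stats::rnorm(n, 41, 10), 15)
    ldl <- pmax(stats::rnorm(n, 128, 35), 30)
    b_age <- 0.2; b_bmi <- 0.15
    alpha <- log(config$target_prevalence) -
      (config$prevalence_beta^2 + b_age^2 + b_bmi^2) / 2
    p_prev <- pmin(exp(alpha + config$prevalence_beta * s +
                         b_age * z_age + b_bmi * z_bmi), 0.95)
    prevalent <- stats::rbinom(n, 1, p_prev)
    fpg <- fpg + prevalent * 70
    g2h <- g2h + prevalent * 140
    rate <- config$baseline_hazard *
      exp(config$hazard_beta * s + 0.15 * z_age + 0.1 * z_bmi)
    t_event <- stats::rexp(n, rate)
    t_drop <- if (config$censoring_rate > 0)
      stats::rexp(n, config$censoring_rate) else rep(Inf, n)
    horizon <- pmin(t_drop, config$followup_years)
    time <- pmin(t_event, horizon)
    event <- as.integer(t_event <= horizon)
    # prevalent cases carry no incident follow-up
    time[prevalent == 1] <- NA_real_
    event[prevalent == 1] <- NA_integer_
    out <- data.frame(
      sample_id = rownames(dos), sex = sex, age = age, bmi = bmi,
      fpg = fpg, g2h = g2h, tc = tc, tg = tg, hdl = hdl, ldl = ldl,
      prevalent_t2d = prevalent, time_years = time, event = event,
      true_score = s, stringsAsFactors = FALSE)
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}

#' Calibrate a per-SD log effect so the true top-vs-bottom quintile ratio
#' hits a target
#'
#' Both outcome models are log-linear in the standardized score, so the
#' true quintile-5-vs-1 rate ratio implied by a per-SD coefficient beta is
#' mean(exp(beta * s) | top quintile) / mean(exp(beta * s) | bottom
#' quintile) over the realized score distribution. Given the scores of a
#' simulated cohort, this solves for the beta whose implied ratio equals
#' `target_ratio` exactly, removing the small distortion a normal-theory
#' constant (log ratio / 2.8016) leaves when the score is not exactly
#' Gaussian.
#'
#' @param scores numeric vector of (standardized) true scores.
#' @param target_ratio desired true quintile-5-vs-1 rate ratio.
#' @return the per-SD log-ratio coefficient.
#' @export
calibrate_quintile_effect <- function(scores, target_ratio) {
  q <- assign_quintiles(scores)$quintile
  s1 <- scores[q == 1]
  s5 <- scores[q == 5]
  f <- function(b) log(mean(exp(b * s5)) / mean(exp(b * s1))) -
    log(target_ratio)
  stats::uniroot(f, c(0, 5), tol = 1e-10)$root
}

#' Plant opposite-direction enrichment groups into a frequency table
#'
#' Shifts the frequency of two disjoint SNP groups up in half of the
#' populations and down in the other half, with opposite assignment for the
#' two groups. Used to verify that the enrichment heatmap's two-cluster cut
#' recovers planted structure.
#'
#' @param pop_freqs n_snps x n_populations frequency matrix.
#' @param group_a,group_b integer vectors of (disjoint) SNP row indices.
#' @param delta frequency shift magnitude.
#' @param pops_up character vector of populations shifted up for group A
#'   (default: first half of the columns).
#' @return modified frequency matrix, clipped to [0.01, 0.99].
#' @export
plant_enrichment_groups <- function(pop_freqs, group_a, group_b, delta = 0.15,
                                    pops_up = NULL) {
  stopifnot(length(intersect(group_a, group_b)) == 0)
  pops <- colnames(pop_freqs)
  if (is.null(pops_up)) pops_up <- pops[seq_len(floor(length(pops) / 2))]
  pops_down <- setdiff(pops, pops_up)
  clip <- function(x) pmin(pmax(x, 0.01), 0.99)
  pop_freqs[group_a, pops_up] <- clip(pop_freqs[group_a, pops_up] + delta)
  pop_freqs[group_a, pops_down] <- clip(pop_freqs[group_a, pops_down] - delta)
  pop_freqs[group_b, pops_up] <- clip(pop_freqs[group_b, pops_up] - delta)
  pop_freqs[group_b, pops_down] <- clip(pop_freqs[group_b, pops_down] + delta)
  pop_freqs
}

#' Simulate a complete dataset and optionally write it to disk
#'
#' Runs the frequency, genotype, GWAS-table and phenotype generators in
#' sequence from the single master seed. When `out_dir` is given, writes
#' the VCF (GT only), the sample->population panel TSV, the GWAS summary
#' TSV and the phenotype CSV there.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @param phenotype_population population whose samples get phenotypes
#'   (default "IR"; use NULL for all samples).
#' @return list with `genotypes`, `gwas`, `phenotypes`, `pop_freqs`,
#'   `ancestral`, and (if written) `paths`.
#' @export
simulate_dataset <- function(config, out_dir = NULL,
                             phenotype_population = "IR") {
  freq <- simulate_frequency_table(config)
  gm <- simulate_genotypes(freq$pop_freqs, config)
  gwas <- simulate_gwas_table(gm$variants, config)
  weights <- attr(gwas, "risk_weights")
  pheno_gm <- if (is.null(phenotype_population)) gm else
    subset_genotypes(gm, samples = gm$panel$sample_id[
      gm$panel$population == phenotype_population])
  pheno <- simulate_phenotypes(pheno_gm, weights, config)
  out <- list(genotypes = gm, gwas = gwas, phenotypes = pheno,
              pop_freqs = freq$pop_freqs, ancestral = freq$ancestral)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = file.path(out_dir, "genotypes.vcf"),
      panel = file.path(out_dir, "panel.tsv"),
      gwas = file.path(out_dir, "gwas_summary.tsv"),
      phenotypes = file.path(out_dir, "phenotypes.csv"))
    write_vcf(gm, paths$vcf)
    utils::write.table(gm$panel, paths$panel, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(gwas, paths$gwas, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.csv(pheno, paths$phenotypes, row.names = FALSE)
    out$paths <- paths
  }
  out
}
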