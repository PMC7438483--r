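#' Pipeline run configuration
#'
#' Collects the input paths and every stage parameter with its canonical
#' default: genome-wide significance 5e-8, risk-allele OR floor 1.2, FDR
#' alpha 0.05, high-Fst floor 0.05 with a top-1% pooled quantile, clumping
#' r^2 0.1 within a 250-kb window. The configuration is serialized into
#' the run manifest.
#'
#' @param vcf,panel,gwas,phenotypes input file paths.
#' @param out_dir output directory for all stage outputs.
#' @param target_population population scored and analysed downstream.
#' @param p_threshold,or_floor,fdr_alpha,fst_floor,top_quantile,r2_threshold,window_bp,freq_bin_width
#'   stage parameters.
#' @param score_snps "enriched" (default: score the SNPs significantly
#'   enriched in the target population) or "all_risk".
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf, panel, gwas, phenotypes, out_dir,
                       target_population = "IR",
                       p_threshold = 5e-8, or_floor = 1.2, fdr_alpha = 0.05,
                       fst_floor = 0.05, top_quantile = 0.01,
                       r2_threshold = 0.1, window_bp = 250000,
                       freq_bin_width = 0.02,
                       score_snps = c("enriched", "all_risk"),
                       seed = 1L) {
  structure(list(vcf = vcf, panel = panel, gwas = gwas,
                 phenotypes = phenotypes, out_dir = out_dir,
                 target_population = target_population,
                 p_threshold = p_threshold, or_floor = or_floor,
                 fdr_alpha = fdr_alpha, fst_floor = fst_floor,
                 top_quantile = top_quantile, r2_threshold = r2_threshold,
                 window_bp = window_bp, freq_bin_width = freq_bin_width,
                 score_snps = match.arg(score_snps), seed = as.integer(seed)),
            class = "run_config")
}

pipeline_stages <- function() {
  list(catalog = character(0),
       freqs = "catalog",
       fst = "freqs",
       pca = "catalog",
       enrich = "freqs",
       clump = "enrich",
       score = "clump",
       assoc = "score")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (catalog -> freqs -> fst/pca/enrich -> clump -> score -> assoc), writing
#' each stage's outputs as TSV/JSON under `config$out_dir` and a run
#' manifest (parameters, seed, package version, per-file MD5 checksums) as
#' `manifest.json`. A stage whose upstream outputs are missing fails with
#' an error naming the stage to run first. Reruns with the same config and
#' inputs are byte-identical for the deterministic stages.
#'
#' @param config a [run_config()].
#' @param stages character vector of stages to run, or "all".
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, stages = "all") {
  stopifnot(inherits(config, "run_config"))
  deps <- pipeline_stages()
  all_stages <- names(deps)
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ", paste(setdiff(stages, all_stages), collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage_done <- function(s) {
    marker <- c(catalog = "harmonized_catalog.tsv", freqs = "frequencies.tsv",
                fst = "selection_test.json", pca = "pca_scores.tsv",
                enrich = "enrichment.tsv", clump = "index_snps.tsv",
                score = "prs.tsv", assoc = "hazard_ratios.tsv")
    file.exists(out(marker[[s]]))
  }
  for (s in stages) {
    missing_dep <- setdiff(deps[[s]], stages)
    missing_dep <- missing_dep[!vapply(missing_dep, stage_done, TRUE)]
    if (length(missing_dep))
      stop("stage '", s, "' needs upstream stage(s) not yet run: ",
           paste(missing_dep, collapse = ", "),
           ". Run those first or include them in `stages`.")
  }
  stages <- all_stages[all_stages %in% stages]   # dependency order

  env <- new.env(parent = emptyenv())
  load_genotypes <- function() {
    if (is.null(env$gm)) env$gm <- read_vcf_genotypes(config$vcf, config$panel)
    env$gm
  }
  load_catalog <- function() {
    if (is.null(env$catalog)) {
      if (!stage_done("catalog")) stop("run stage 'catalog' first")
      rec <- utils::read.delim(out("harmonized_catalog.tsv"),
                               stringsAsFactors = FALSE,
                               colClasses = c(snp_id = "character",
                                              gene = "character"))
      env$catalog <- structure(
        list(records = rec, risk_subset = rec[rec$is_risk, , drop = FALSE],
             exclusions = NULL, p_threshold = config$p_threshold,
             or_floor = config$or_floor),
        class = "harmonized_catalog")
    }
    env$catalog
  }
  load_freqs <- function() {
    if (is.null(env$freqs)) {
      if (!stage_done("freqs")) stop("run stage 'freqs' first")
      fr <- utils::read.delim(out("frequencies.tsv"), stringsAsFactors = FALSE,
                              colClasses = c(snp_id = "character"))
      class(fr) <- c("frequency_table", "data.frame")
      env$freqs <- fr
    }
    env$freqs
  }

  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  for (s in stages) {
    message("[t2dburden] stage: ", s)
    if (s == "catalog") {
      raw <- read_gwas_summary(config$gwas)
      cat <- harmonize(raw, p_threshold = config$p_threshold,
                       or_floor = config$or_floor)
      env$catalog <- cat
      emit(write_tsv(cat$records, out("harmonized_catalog.tsv")))
      emit(write_tsv(cat$exclusions, out("catalog_exclusions.tsv")))
    } else if (s == "freqs") {
      fr <- allele_frequencies(load_genotypes(), load_catalog())
      env$freqs <- fr
      emit(write_tsv(as.data.frame(fr), out("frequencies.tsv")))
      excl <- attr(fr, "exclusions")
      if (!is.null(excl) && nrow(excl))
        emit(write_tsv(excl, out("frequency_exclusions.tsv")))
    } else if (s == "fst") {
      gm <- load_genotypes()
      cat <- load_catalog()
      target_ids <- cat$records$snp_id
      pool_ids <- setdiff(gm$variants$snp_id, target_ids)
      if (length(pool_ids) < length(target_ids))
        stop("background pool too small for frequency-matched sampling")
      # match on pooled minor-allele frequency (allele-symmetric, like Fst)
      alt_freq <- colMeans(gm$dosages, na.rm = TRUE) / 2
      maf <- pmin(alt_freq, 1 - alt_freq)
      names(maf) <- gm$variants$snp_id
      matched <- sample_frequency_matched(
        maf[target_ids], maf[pool_ids], bin_width = config$freq_bin_width,
        seed = substream_seed(config$seed, "fst_null"))
      fst_t2d <- fst_pairwise(gm, snp_ids = target_ids)
      fst_rand <- fst_pairwise(gm, snp_ids = matched)
      emit(write_tsv(fst_t2d, out("fst_pairwise.tsv")))
      pair_means <- stats::aggregate(
        theta ~ pop_a + pop_b, data = fst_t2d[!fst_t2d$undefined, ],
        FUN = mean)
      emit(write_tsv(pair_means, out("fst_pair_means.tsv")))
      sel <- high_fst_selection_test(
        summarize_fst_max(fst_t2d), summarize_fst_max(fst_rand),
        fst_floor = config$fst_floor, top_quantile = config$top_quantile)
      jsonlite::write_json(sel, out("selection_test.json"), auto_unbox = TRUE,
                           digits = NA)
      emit(out("selection_test.json"))
    } else if (s == "pca") {
      gm <- load_genotypes()
      cat <- load_catalog()
      ids <- intersect(cat$records$snp_id, gm$variants$snp_id)
      pc <- genotype_pca(subset_genotypes(gm, snps = ids))
      sc <- data.frame(sample_id = rownames(pc$scores),
                       population = pc$populations, pc$scores,
                       stringsAsFactors = FALSE)
      emit(write_tsv(sc, out("pca_scores.tsv")))
      emit(write_tsv(data.frame(component = seq_along(pc$explained),
                                explained = pc$explained),
                     out("pca_explained.tsv")))
    } else if (s == "enrich") {
      enr <- test_enrichment(load_catalog(), load_freqs(),
                             alpha = config$fdr_alpha)
      env$enrich <- enr
      emit(write_tsv(as.data.frame(enr), out("enrichment.tsv")))
      emit(write_tsv(gene_level_counts(enr, top = 4), out("gene_counts.tsv")))
      hm <- tryCatch(heatmap_matrix(enr), error = function(e) NULL)
      if (!is.null(hm)) {
        emit(write_tsv(data.frame(snp_id = rownames(hm$matrix),
                                  cluster = hm$clusters, hm$matrix,
                                  check.names = FALSE),
                       out("heatmap_matrix.tsv")))
      }
    } else if (s == "clump") {
      if (is.null(env$enrich)) {
        if (!stage_done("enrich")) stop("run stage 'enrich' first")
        env$enrich <- utils::read.delim(out("enrichment.tsv"),
                                        stringsAsFactors = FALSE,
                                        colClasses = c(snp_id = "character"))
      }
      cat <- load_catalog()
      risk <- cat$risk_subset
      if (config$score_snps == "enriched") {
        enr <- env$enrich
        keep <- unique(enr$snp_id[enr$population == config$target_population &
                                    enr$significant &
                                    enr$direction == "enriched"])
        risk <- risk[risk$snp_id %in% keep, , drop = FALSE]
      }
      if (nrow(risk) == 0) stop("no SNPs to clump (no enriched risk SNPs?)")
      gm <- load_genotypes()
      ref <- subset_genotypes(gm, samples = gm$panel$sample_id[
        gm$panel$population == config$target_population])
      idx <- ld_clump(risk, ref, clump_config(config$r2_threshold,
                                              config$window_bp))
      env$index <- risk[risk$snp_id %in% idx, , drop = FALSE]
      emit(write_tsv(env$index, out("index_snps.tsv")))
    } else if (s == "score") {
      if (is.null(env$index)) {
        if (!stage_done("clump")) stop("run stage 'clump' first")
        env$index <- utils::read.delim(out("index_snps.tsv"),
                                       stringsAsFactors = FALSE,
                                       colClasses = c(snp_id = "character"))
      }
      gm <- load_genotypes()
      target <- subset_genotypes(gm, samples = gm$panel$sample_id[
        gm$panel$population == config$target_population])
      prs <- compute_prs(target, env$index)
      q <- assign_quintiles(prs$score)
      prs$quintile <- q$quintile
      prs$category <- as.character(q$category)
      env$prs <- prs
      emit(write_tsv(prs, out("prs.tsv")))
    } else if (s == "assoc") {
      if (is.null(env$prs)) {
        if (!stage_done("score")) stop("run stage 'score' first")
        env$prs <- utils::read.delim(out("prs.tsv"), stringsAsFactors = FALSE)
      }
      pheno <- utils::read.csv(config$phenotypes, stringsAsFactors = FALSE)
      cohort <- build_cohort(pheno, env$prs[, c("sample_id", "score",
                                                "n_snps_used")])
      pr <- prevalence_ratios(cohort)
      emit(write_tsv(pr, out("prevalence_ratios.tsv")))
      hr <- hazard_ratios(cohort)
      hr_full <- hazard_ratios(cohort, covariates = c("age", "sex", "bmi",
                                                      "fpg", "g2h", "tc",
                                                      "tg", "hdl", "ldl"))
      hr$model <- "age_sex_bmi"
      hr_full$model <- "full"
      emit(write_tsv(rbind(hr, hr_full), out("hazard_ratios.tsv")))
      emit(write_tsv(cumulative_incidence(cohort),
                     out("cumulative_incidence.tsv")))
      emit(write_tsv(biomarker_associations(cohort, "fpg"),
                     out("biomarker_fpg.tsv")))
    }
  }

  manifest <- list(
    package = "t2dburden",
    version = as.character(utils::packageVersion("t2dburden")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    stages = stages,
    checksums = as.list(tools::md5sum(sort(unique(written)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Command-line entry point
#'
#' A minimal argument-vector interface so the pipeline can be driven as
#' `Rscript -e 't2dburden::pipeline_cli()' -- simulate|run-all ...`.
#' Subcommands: `simulate` (write a synthetic dataset) and `run-all`
#' (run every analysis stage), plus any single stage name.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: <simulate|run-all|catalog|freqs|fst|pca|enrich|clump|score|assoc>",
    "--dir DIR [--seed N] [--n-snps N] [--n-samples-per-pop N]",
    sep = "\n  ")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  dir <- opt("--dir", "t2dburden_run")
  seed <- as.integer(opt("--seed", "1"))
  if (cmd == "simulate") {
    n_snps <- as.integer(opt("--n-snps", "2000"))
    nper <- as.integer(opt("--n-samples-per-pop", "200"))
    pops <- lapply(default_populations(), function(p)
      population_spec(p$name, nper, p$fst_to_ancestral))
    cfg <- sim_config(n_snps = n_snps,
                      n_catalog_snps = min(1000L, n_snps %/% 2),
                      n_risk_snps = min(212L, n_snps %/% 10),
                      populations = pops, seed = seed)
    simulate_dataset(cfg, out_dir = file.path(dir, "input"))
    message("simulated dataset written to ", file.path(dir, "input"))
    return(invisible(0L))
  }
  inp <- file.path(dir, "input")
  cfg <- run_config(vcf = file.path(inp, "genotypes.vcf"),
                    panel = file.path(inp, "panel.tsv"),
                    gwas = file.path(inp, "gwas_summary.tsv"),
                    phenotypes = file.path(inp, "phenotypes.csv"),
                    out_dir = file.path(dir, "output"), seed = seed)
  stages <- if (cmd == "run-all") "all" else cmd
  run_pipeline(cfg, stages = stages)
  invisible(0L)
}
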