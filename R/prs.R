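#' LD clumping configuration
#'
#' @param r2_threshold squared-correlation threshold above which a
#'   neighbouring SNP is absorbed by an index SNP (default 0.1).
#' @param window_bp window half-width in base pairs (default 250,000).
#' @return list of class `clump_config`.
#' @export
clump_config <- function(r2_threshold = 0.1, window_bp = 250000) {
  if (r2_threshold <= 0 || r2_threshold > 1) stop("r2_threshold must be in (0,1]")
  if (window_bp <= 0) stop("window_bp must be positive")
  structure(list(r2_threshold = r2_threshold, window_bp = window_bp),
            class = "clump_config")
}

#' Greedy LD clumping of summary SNPs against a reference panel
#'
#' SNPs are visited in ascending p-value (ties broken by position, then
#' id). A visited SNP that has not been removed becomes an index SNP; all
#' not-yet-visited SNPs on the same chromosome within +/- window_bp whose
#' squared Pearson dosage correlation with the index exceeds r2_threshold
#' are removed. Squared correlation is computed from the reference panel
#' dosages (composite LD, no phasing needed). Summary SNPs absent from the
#' reference are excluded with a warning.
#'
#' @param summary data.frame with snp_id, chr (or chrom), pos, pvalue.
#' @param reference a [genotype_matrix()] providing LD.
#' @param config a [clump_config()].
#' @return character vector of retained index snp ids in genomic order,
#'   with attribute `removed_by` (named vector: removed SNP -> index SNP).
#' @export
ld_clump <- function(summary, reference, config = clump_config()) {
  stopifnot(inherits(reference, "genotype_matrix"))
  chrcol <- if ("chr" %in% names(summary)) "chr" else "chrom"
  s <- data.frame(snp_id = summary$snp_id, chrom = as.character(summary[[chrcol]]),
                  pos = summary$pos, pvalue = summary$pvalue,
                  stringsAsFactors = FALSE)
  present <- s$snp_id %in% reference$variants$snp_id
  if (!all(present)) {
    warning(sum(!present), " summary SNP(s) absent from reference, excluded")
    s <- s[present, , drop = FALSE]
  }
  if (nrow(s) == 0) stop("no summary SNPs present in the reference")
  D <- reference$dosages[, s$snp_id, drop = FALSE]
  ord <- order(s$pvalue, s$pos, s$snp_id)
  state <- rep("free", nrow(s))          # free | index | removed
  removed_by <- character(0)
  for (i in ord) {
    if (state[i] != "free") next
    state[i] <- "index"
    near <- which(state == "free" & s$chrom == s$chrom[i] &
                    abs(s$pos - s$pos[i]) <= config$window_bp)
    if (length(near) == 0) next
    r <- suppressWarnings(stats::cor(D[, i], D[, near, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    r2 <- as.numeric(r)^2
    hit <- near[!is.na(r2) & r2 > config$r2_threshold]
    if (length(hit)) {
      state[hit] <- "removed"
      removed_by <- c(removed_by,
                      stats::setNames(rep(s$snp_id[i], length(hit)),
                                      s$snp_id[hit]))
    }
  }
  idx <- which(state == "index")
  idx <- idx[order(s$chrom[idx], s$pos[idx])]
  out <- s$snp_id[idx]
  attr(out, "removed_by") <- removed_by
  out
}

#' Compute the weighted polygenic risk score
#'
#' score_i = sum_j ln(OR_j) * dosage_ij over the index SNPs, where the
#' dosage counts effect alleles. Missing dosages are mean-imputed as twice
#' the cohort effect-allele frequency at the SNP. The effect allele is
#' matched to the variant's ref or alt allele; when it is the ref allele
#' the dosage is reversed (2 - alt dosage).
#'
#' @param genotypes a [genotype_matrix()] for the scored cohort.
#' @param index_snps data.frame with snp_id, effect_allele, or (odds
#'   ratio) — typically the harmonized risk subset restricted to clumped
#'   index SNPs.
#' @return data.frame (class `prs_result`) with sample_id, score,
#'   n_snps_used.
#' @export
compute_prs <- function(genotypes, index_snps) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  m <- match(index_snps$snp_id, v$snp_id)
  ok <- !is.na(m)
  if (!all(ok)) {
    warning(sum(!ok), " index SNP(s) absent from genotypes, skipped")
    index_snps <- index_snps[ok, , drop = FALSE]
    m <- m[ok]
  }
  is_alt <- index_snps$effect_allele == v$alt[m]
  is_ref <- index_snps$effect_allele == v$ref[m]
  mism <- !(is_alt | is_ref)
  if (any(mism)) {
    warning(sum(mism), " index SNP(s) with allele mismatch, skipped")
    index_snps <- index_snps[!mism, , drop = FALSE]
    m <- m[!mism]
    is_alt <- is_alt[!mism]
  }
  if (nrow(index_snps) == 0) stop("zero usable index SNPs")
  D <- genotypes$dosages[, m, drop = FALSE]
  D[, !is_alt] <- 2 - D[, !is_alt, drop = FALSE]
  n_used <- rowSums(!is.na(D))
  eff_freq <- colMeans(D, na.rm = TRUE) / 2
  for (j in which(colSums(is.na(D)) > 0))
    D[is.na(D[, j]), j] <- 2 * eff_freq[j]
  w <- log(index_snps$or)
  score <- as.numeric(D %*% w)
  out <- data.frame(sample_id = rownames(genotypes$dosages), score = score,
                    n_snps_used = n_used, stringsAsFactors = FALSE)
  class(out) <- c("prs_result", "data.frame")
  out
}

#' Assign score quintiles and genetic-risk categories
#'
#' Cut points are the empirical 20/40/60/80 percentiles (linear
#' interpolation, R quantile type 7). A score exactly equal to a boundary
#' goes to the lower quintile. Categories: low = quintile 1, moderate =
#' quintiles 2-4, high = quintile 5.
#'
#' @param scores numeric vector with at least 5 distinct values.
#' @return data.frame with quintile (integer 1-5) and category (factor
#'   low/moderate/high), rows in input order.
#' @export
assign_quintiles <- function(scores) {
  if (length(scores) < 5) stop("need at least 5 samples")
  if (length(unique(scores)) < 5)
    stop("degenerate scores: fewer than 5 distinct values")
  cuts <- stats::quantile(scores, c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE)
  q <- findInterval(scores, cuts, left.open = TRUE) + 1L
  cat <- factor(ifelse(q == 1, "low", ifelse(q == 5, "high", "moderate")),
                levels = c("low", "moderate", "high"))
  data.frame(quintile = q, category = cat)
}
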