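#' Weir-Cockerham Fst from genotype counts (two populations, per locus)
#'
#' Implements the 1984 variance-components estimator for two populations at
#' one biallelic locus, using observed heterozygote counts. Inputs are
#' genotype counts (n0, n1, n2) = counts of dosage 0/1/2 individuals; rows
#' are loci. The estimate is theta = a / (a + b + c) where a, b, c are the
#' among-population, among-individual and within-individual variance
#' components. theta is undefined (flagged) when the denominator is zero
#' (both populations monomorphic for the same allele) or when either
#' population has fewer than two genotyped individuals.
#'
#' @param counts1,counts2 numeric vectors of length 3 (one locus) or
#'   matrices with 3 columns (n0, n1, n2), one row per locus.
#' @return data.frame with columns a, b, c, theta, undefined.
#' @export
wc_fst <- function(counts1, counts2) {
  if (is.null(dim(counts1))) counts1 <- matrix(counts1, nrow = 1)
  if (is.null(dim(counts2))) counts2 <- matrix(counts2, nrow = 1)
  stopifnot(ncol(counts1) == 3, ncol(counts2) == 3,
            nrow(counts1) == nrow(counts2))
  if (any(counts1 < 0) || any(counts2 < 0)) stop("negative genotype counts")
  n1 <- rowSums(counts1); n2 <- rowSums(counts2)
  p1 <- (counts1[, 2] + 2 * counts1[, 3]) / (2 * n1)
  p2 <- (counts2[, 2] + 2 * counts2[, 3]) / (2 * n2)
  h1 <- counts1[, 2] / n1
  h2 <- counts2[, 2] / n2
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  undefined <- n1 < 2 | n2 < 2 | denom == 0 | !is.finite(denom)
  theta <- ifelse(undefined, NA_real_, a / denom)
  data.frame(a = a, b = b, c = cc, theta = theta, undefined = undefined)
}

dosage_counts <- function(dosages) {
  # samples x variants -> variants x 3 genotype-count matrix
  cbind(n0 = colSums(dosages == 0, na.rm = TRUE),
        n1 = colSums(dosages == 1, na.rm = TRUE),
        n2 = colSums(dosages == 2, na.rm = TRUE))
}

#' Pairwise per-SNP Fst across all population pairs of a genotype matrix
#'
#' @param genotypes a [genotype_matrix()].
#' @param snp_ids optional subset of variant ids (default all).
#' @param pairs optional 2-column character matrix of population pairs;
#'   default all unordered pairs in the panel.
#' @return data.frame with snp_id, pop_a, pop_b, a, b, c, theta, undefined.
#' @export
fst_pairwise <- function(genotypes, snp_ids = NULL, pairs = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  gm <- if (is.null(snp_ids)) genotypes else subset_genotypes(genotypes, snps = snp_ids)
  pops <- sort(unique(gm$panel$population))
  if (is.null(pairs)) {
    if (length(pops) < 2) stop("need at least two populations")
    pairs <- t(utils::combn(pops, 2))
  }
  cnt <- lapply(stats::setNames(pops, pops), function(p) {
    dosage_counts(gm$dosages[gm$panel$sample_id[gm$panel$population == p], ,
                             drop = FALSE])
  })
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    res <- wc_fst(cnt[[pairs[k, 1]]], cnt[[pairs[k, 2]]])
    cbind(data.frame(snp_id = gm$variants$snp_id,
                     pop_a = pairs[k, 1], pop_b = pairs[k, 2],
                     stringsAsFactors = FALSE), res)
  }))
}

#' Mean Fst over loci
#'
#' Arithmetic mean of the defined per-SNP theta estimates (the primary
#' summary), with the ratio-of-sums estimator sum(a)/sum(a+b+c) reported as
#' a secondary field.
#'
#' @param results data.frame from [wc_fst()] / [fst_pairwise()] (columns a,
#'   b, c, theta) or a numeric vector of theta values.
#' @return list with `mean_theta`, `ratio_of_sums` (NA for vector input)
#'   and `n_defined`.
#' @export
mean_fst <- function(results) {
  if (is.numeric(results)) {
    th <- results[!is.na(results)]
    if (length(th) == 0) stop("no defined Fst estimates")
    return(list(mean_theta = mean(th), ratio_of_sums = NA_real_,
                n_defined = length(th)))
  }
  ok <- !results$undefined & !is.na(results$theta)
  if (!any(ok)) stop("no defined Fst estimates")
  list(mean_theta = mean(results$theta[ok]),
       ratio_of_sums = sum(results$a[ok]) /
         sum(results$a[ok] + results$b[ok] + results$c[ok]),
       n_defined = sum(ok))
}

#' Frequency-matched random SNP sampling
#'
#' Draws, for each target SNP, one pool SNP without replacement from the
#' same allele-frequency bin (default width 0.02), producing a random SNP
#' set whose frequency spectrum matches the target set. Exhausted bins
#' fall back to the nearest non-empty neighbouring bin with a warning.
#'
#' @param target_freqs named numeric vector (names = snp ids) of target
#'   frequencies.
#' @param pool_freqs named numeric vector of candidate-pool frequencies;
#'   names must be unique.
#' @param bin_width frequency bin width.
#' @param seed integer seed.
#' @return character vector of sampled pool snp ids, same length as target.
#' @export
sample_frequency_matched <- function(target_freqs, pool_freqs,
                                     bin_width = 0.02, seed = 1L) {
  stopifnot(!is.null(names(pool_freqs)), !anyDuplicated(names(pool_freqs)))
  bin_of <- function(f) pmin(floor(f / bin_width), floor(1 / bin_width))
  t_bin <- bin_of(target_freqs)
  p_bin <- bin_of(pool_freqs)
  available <- rep(TRUE, length(pool_freqs))
  picked <- character(length(target_freqs))
  n_fallback <- 0L
  with_seed(seed, {
    for (i in seq_along(target_freqs)) {
      cand <- which(available & p_bin == t_bin[i])
      if (length(cand) == 0) {
        avail_bins <- unique(p_bin[available])
        if (length(avail_bins) == 0) stop("pool exhausted")
        nearest <- avail_bins[which.min(abs(avail_bins - t_bin[i]))]
        cand <- which(available & p_bin == nearest)
        n_fallback <- n_fallback + 1L
      }
      j <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
      available[j] <- FALSE
      picked[i] <- names(pool_freqs)[j]
    }
  })
  if (n_fallback > 0)
    warning(n_fallback, " target SNP(s) matched from a neighbouring bin")
  picked
}

#' Per-SNP summary Fst: maximum over pairwise comparisons
#'
#' @param fst_long data.frame from [fst_pairwise()].
#' @return named numeric vector, one value per SNP (NA if all pairs
#'   undefined).
#' @export
summarize_fst_max <- function(fst_long) {
  th <- fst_long$theta
  out <- tapply(th, fst_long$snp_id, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  out[unique(fst_long$snp_id)]
}

#' High-Fst selection test against a frequency-matched random set
#'
#' A SNP is "high-Fst" when its summary Fst (maximum over pairwise
#' comparisons) exceeds `fst_floor` AND lies above the (1 - top_quantile)
#' quantile of the pooled summary distribution of both sets. The counts of
#' high-Fst SNPs in the trait-associated and random sets are compared with
#' a Pearson chi-square test on the 2x2 table (no continuity correction,
#' 1 df, upper tail).
#'
#' @param t2d_fst numeric vector of per-SNP summary Fst for the
#'   trait-associated set.
#' @param random_fst numeric vector for the matched random set (same
#'   length).
#' @param fst_floor absolute floor, default 0.05.
#' @param top_quantile pooled upper-tail fraction, default 0.01 (top 1%).
#' @return list with n_high_t2d, n_high_random, n_total, chi2, pvalue,
#'   threshold.
#' @export
high_fst_selection_test <- function(t2d_fst, random_fst, fst_floor = 0.05,
                                    top_quantile = 0.01) {
  if (length(t2d_fst) == 0 || length(random_fst) == 0)
    stop("both sets must be non-empty")
  if (length(t2d_fst) != length(random_fst))
    stop("set size mismatch: ", length(t2d_fst), " vs ", length(random_fst))
  pooled <- c(t2d_fst, random_fst)
  thr <- stats::quantile(pooled, 1 - top_quantile, na.rm = TRUE, names = FALSE)
  is_high <- function(x) !is.na(x) & x > fst_floor & x > thr
  k1 <- sum(is_high(t2d_fst)); k2 <- sum(is_high(random_fst))
  n <- length(t2d_fst)
  tab <- matrix(c(k1, n - k1, k2, n - k2), nrow = 2, byrow = TRUE)
  ch <- chisq_2x2(tab)
  list(n_high_t2d = k1, n_high_random = k2, n_total = n,
       chi2 = ch$statistic, pvalue = ch$pvalue, threshold = thr)
}

#' Pearson chi-square on a 2x2 table (no continuity correction, 1 df)
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @return list with `statistic` and upper-tail `pvalue` at 1 df.
#' @export
chisq_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  list(statistic = stat, pvalue = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Genotype principal component analysis
#'
#' Standard PCA for population structure: dosages are mean-imputed per SNP,
#' centered at twice the estimated allele frequency and scaled by
#' sqrt(2 p (1 - p)); monomorphic SNPs are dropped; scores come from the
#' singular value decomposition of the standardized matrix.
#'
#' @param genotypes a [genotype_matrix()].
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `explained`
#'   (variance fractions, sum <= 1), `populations` (panel labels in score
#'   row order).
#' @export
genotype_pca <- function(genotypes, n_components = 10) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  X <- genotypes$dosages
  if (nrow(X) < 2) stop("need at least two samples")
  cm <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- cm[j]
  p_hat <- colMeans(X) / 2
  poly <- p_hat > 0 & p_hat < 1
  if (sum(poly) < 2) stop("need at least two polymorphic SNPs")
  X <- X[, poly, drop = FALSE]
  p_hat <- p_hat[poly]
  Z <- sweep(X, 2, 2 * p_hat, "-")
  Z <- sweep(Z, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  k <- min(n_components, nrow(Z) - 1, ncol(Z))
  # work in the smaller dimension: scores = Z v for eigenvectors v of Z'Z
  if (ncol(Z) <= nrow(Z)) {
    eg <- eigen(crossprod(Z), symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    scores <- Z %*% eg$vectors[, seq_len(k), drop = FALSE]
  } else {
    eg <- eigen(tcrossprod(Z), symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    scores <- eg$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(k)]), k, k)
  }
  rownames(scores) <- rownames(genotypes$dosages)
  colnames(scores) <- paste0("PC", seq_len(k))
  pop <- genotypes$panel$population[match(rownames(scores),
                                          genotypes$panel$sample_id)]
  list(scores = scores, explained = ev[seq_len(k)] / sum(ev),
       populations = pop)
}
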