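#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' all tables whose probability does not exceed that of the observed table
#' (within relative tolerance 1e-7), the classical two-sided definition.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0)) stop("negative counts")
  if (sum(tab) == 0) stop("all margins zero")
  m <- tab[1, 1] + tab[2, 1]        # first-column margin
  n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]        # first-row margin
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  p <- sum(d[d <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Benjamini-Hochberg step-up false discovery rate adjustment
#'
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1; output is in the
#' input order.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must be in [0,1]")
  m <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- pmin(rev(cummin(rev(pvalues[o] * m / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Per-SNP, per-population risk-allele enrichment test
#'
#' For every risk SNP and every population, builds the 2x2 allele-count
#' table [risk, non-risk in the population] vs [risk, non-risk in the
#' pooled global population] and applies the two-sided Fisher exact test.
#' By default the global pool includes the tested population (the pool is
#' all populations together); `leave_one_out = TRUE` removes it. BH
#' adjustment is applied within each population across its SNPs (or across
#' all tests with `fdr_scope = "global"`). A SNP is enriched in a
#' population when its risk-allele frequency exceeds the global frequency,
#' depleted otherwise; significant means q < alpha (strict). The signed
#' score is -log10(q) for enriched and +log10(q) (a negative number) for
#' depleted SNPs.
#'
#' @param catalog a `harmonized_catalog`; its `risk_subset` is tested.
#' @param freqs a `frequency_table` from [allele_frequencies()] including
#'   the "GLOBAL" pool rows.
#' @param alpha FDR significance cutoff (default 0.05).
#' @param leave_one_out exclude the tested population from the global pool.
#' @param fdr_scope "population" (default) or "global".
#' @return data.frame (class `enrichment_result`) with snp_id, population,
#'   gene, pop_risk, pop_nonrisk, glob_risk, glob_nonrisk, direction,
#'   pvalue, qvalue, significant, signed_score.
#' @export
test_enrichment <- function(catalog, freqs, alpha = 0.05,
                            leave_one_out = FALSE,
                            fdr_scope = c("population", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  risk <- if (inherits(catalog, "harmonized_catalog")) catalog$risk_subset else catalog
  pops <- setdiff(unique(freqs$population), "GLOBAL")
  if (!"GLOBAL" %in% freqs$population)
    stop("frequency table lacks the pooled GLOBAL population")
  f <- freqs[freqs$snp_id %in% risk$snp_id, , drop = FALSE]
  skipped <- setdiff(risk$snp_id, f$snp_id)
  rows <- list()
  for (pop in pops) {
    fp <- f[f$population == pop, , drop = FALSE]
    fg <- f[f$population == "GLOBAL", , drop = FALSE]
    m <- merge(fp, fg, by = "snp_id", suffixes = c("_pop", "_glob"))
    if (nrow(m) == 0) next
    gr <- m$effect_count_glob
    gt <- m$total_count_glob
    if (leave_one_out) {
      gr <- gr - m$effect_count_pop
      gt <- gt - m$total_count_pop
    }
    pr <- m$effect_count_pop
    pt <- m$total_count_pop
    pv <- vapply(seq_len(nrow(m)), function(i) {
      fisher_exact_2x2(matrix(c(pr[i], pt[i] - pr[i],
                                gr[i], gt[i] - gr[i]), 2, 2, byrow = TRUE))
    }, numeric(1))
    rows[[pop]] <- data.frame(
      snp_id = m$snp_id, population = pop,
      pop_risk = pr, pop_nonrisk = pt - pr,
      glob_risk = gr, glob_nonrisk = gt - gr,
      direction = ifelse(pr / pt > gr / gt, "enriched", "depleted"),
      pvalue = pv, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable SNP/population combinations")
  if (fdr_scope == "population") {
    out$qvalue <- stats::ave(out$pvalue, out$population, FUN = bh_fdr)
  } else {
    out$qvalue <- bh_fdr(out$pvalue)
  }
  out$significant <- out$qvalue < alpha
  # q-values can underflow to 0 at extreme counts; floor keeps the signed
  # score finite
  q_floor <- pmax(out$qvalue, 1e-300)
  out$signed_score <- ifelse(out$direction == "enriched", -log10(q_floor),
                             log10(q_floor))
  gene_map <- stats::setNames(risk$gene %||% rep("", nrow(risk)), risk$snp_id)
  out$gene <- unname(gene_map[out$snp_id])
  if (length(skipped))
    attr(out, "skipped") <- skipped
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Gene-level counts of significantly enriched and depleted risk SNPs
#'
#' @param results an `enrichment_result` from [test_enrichment()].
#' @param top keep the top-n genes per population and direction (NULL =
#'   all). Ranking is by count, ties broken alphabetically by gene.
#' @return data.frame with population, direction, gene, n_snps, rank.
#'   Unmapped SNPs (empty gene) are counted under "intergenic".
#' @export
gene_level_counts <- function(results, top = NULL) {
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(population = character(0), direction = character(0),
                      gene = character(0), n_snps = integer(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  gene <- ifelse(is.na(sig$gene) | sig$gene == "", "intergenic", sig$gene)
  agg <- stats::aggregate(list(n_snps = sig$snp_id),
                          by = list(population = sig$population,
                                    direction = sig$direction, gene = gene),
                          FUN = length)
  agg <- agg[order(agg$population, agg$direction, -agg$n_snps, agg$gene), ]
  agg$rank <- stats::ave(agg$n_snps, agg$population, agg$direction,
                         FUN = seq_along)
  if (!is.null(top)) agg <- agg[agg$rank <= top, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Signed enrichment heatmap matrix with hierarchical row order
#'
#' Builds the SNP x population matrix of signed scores (0 where not
#' significant), restricted to SNPs significant in at least one
#' population, and orders rows by agglomerative clustering (Euclidean
#' distance, complete linkage). The two-cluster cut is reported so
#' co-directional SNP groups can be read off.
#'
#' @param results an `enrichment_result` from [test_enrichment()].
#' @return list with `matrix` (rows in dendrogram order), `row_order`,
#'   `clusters` (named two-cluster assignment, in matrix row order) and
#'   `hclust` (the clustering object).
#' @export
heatmap_matrix <- function(results) {
  sig_snps <- unique(results$snp_id[results$significant])
  if (length(sig_snps) == 0) stop("no significant results to plot")
  sub <- results[results$snp_id %in% sig_snps, , drop = FALSE]
  score <- ifelse(sub$significant, sub$signed_score, 0)
  pops <- sort(unique(sub$population))
  M <- matrix(0, length(sig_snps), length(pops),
              dimnames = list(sort(sig_snps), pops))
  M[cbind(match(sub$snp_id, rownames(M)), match(sub$population, pops))] <- score
  if (all(M == 0)) stop("all-zero heatmap matrix")
  if (nrow(M) == 1) {
    return(list(matrix = M, row_order = rownames(M),
                clusters = stats::setNames(1L, rownames(M)), hclust = NULL))
  }
  hc <- stats::hclust(stats::dist(M, method = "euclidean"),
                      method = "complete")
  cl <- stats::cutree(hc, k = 2)
  ord <- hc$order
  list(matrix = M[ord, , drop = FALSE], row_order = rownames(M)[ord],
       clusters = cl[ord], hclust = hc)
}
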