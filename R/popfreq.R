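#' Per-population effect-allele frequencies
#'
#' For each catalog SNP resolvable in the genotype matrix, counts effect
#' alleles per population and over the pooled global population (all
#' populations together). The effect allele is matched to the variant's
#' ref or alt allele; when it matches ref, the frequency is the complement
#' of the alt-dosage frequency. Missing dosages are excluded from the
#' denominator. SNPs whose effect allele matches neither ref nor alt are
#' excluded and logged.
#'
#' @param genotypes a [genotype_matrix()].
#' @param catalog a `harmonized_catalog` (see [harmonize()]) or a
#'   data.frame with snp_id, effect_allele, other_allele columns.
#' @return object of class `frequency_table`: data.frame with columns
#'   snp_id, population, effect_count, total_count, frequency (long
#'   format; the pooled population is labelled "GLOBAL"), plus an
#'   `exclusions` attribute.
#' @export
allele_frequencies <- function(genotypes, catalog) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  recs <- if (inherits(catalog, "harmonized_catalog")) catalog$records else catalog
  v <- genotypes$variants
  idx <- match(recs$snp_id, v$snp_id)
  found <- !is.na(idx)
  excl <- data.frame(snp_id = recs$snp_id[!found],
                     reason = rep("absent from genotype matrix", sum(!found)),
                     stringsAsFactors = FALSE)
  recs <- recs[found, , drop = FALSE]
  idx <- idx[found]
  is_alt <- recs$effect_allele == v$alt[idx]
  is_ref <- recs$effect_allele == v$ref[idx]
  mism <- !(is_alt | is_ref)
  if (any(mism)) {
    excl <- rbind(excl, data.frame(snp_id = recs$snp_id[mism],
                                   reason = "allele mismatch",
                                   stringsAsFactors = FALSE))
    recs <- recs[!mism, , drop = FALSE]
    idx <- idx[!mism]
    is_alt <- is_alt[!mism]
  }
  pops <- sort(unique(genotypes$panel$population))
  groups <- c(stats::setNames(
    lapply(pops, function(p)
      genotypes$panel$sample_id[genotypes$panel$population == p]), pops),
    list(GLOBAL = genotypes$panel$sample_id))
  out <- do.call(rbind, lapply(names(groups), function(gname) {
    d <- genotypes$dosages[groups[[gname]], idx, drop = FALSE]
    nonmiss <- colSums(!is.na(d))
    alt_count <- colSums(d, na.rm = TRUE)
    total <- 2 * nonmiss
    eff <- ifelse(is_alt, alt_count, total - alt_count)
    data.frame(snp_id = recs$snp_id, population = rep(gname, nrow(recs)),
               effect_count = as.numeric(eff), total_count = as.numeric(total),
               frequency = ifelse(total > 0, eff / total, NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Per-SNP fold differences of effect-allele frequency between populations
#'
#' Reports freq_a / freq_b per SNP. A zero denominator with a nonzero
#' numerator is flagged infinite; 0/0 is undefined and excluded from
#' summaries such as the maximum fold difference.
#'
#' @param freqs a `frequency_table` from [allele_frequencies()].
#' @param pop_a,pop_b population labels (numerator, denominator).
#' @return data.frame with snp_id, freq_a, freq_b, fold (Inf flagged,
#'   0/0 as NA) and logical columns `infinite`, `undefined`.
#' @export
fold_differences <- function(freqs, pop_a, pop_b) {
  pops <- unique(freqs$population)
  if (!pop_a %in% pops) stop("unknown population: ", pop_a)
  if (!pop_b %in% pops) stop("unknown population: ", pop_b)
  a <- freqs[freqs$population == pop_a, c("snp_id", "frequency")]
  b <- freqs[freqs$population == pop_b, c("snp_id", "frequency")]
  m <- merge(a, b, by = "snp_id", suffixes = c("_a", "_b"))
  fold <- ifelse(m$frequency_b > 0, m$frequency_a / m$frequency_b,
                 ifelse(m$frequency_a > 0, Inf, NA_real_))
  data.frame(snp_id = m$snp_id, freq_a = m$frequency_a, freq_b = m$frequency_b,
             fold = fold,
             infinite = is.infinite(fold),
             undefined = is.na(fold),
             stringsAsFactors = FALSE)
}
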