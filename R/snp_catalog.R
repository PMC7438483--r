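#' Read a GWAS association summary table
#'
#' Expects the tab-separated dialect written by the simulator: columns
#' snp_id, chr, pos, effect_allele, other_allele, or, pvalue, strand, gene.
#'
#' @param path path to the TSV file.
#' @return data.frame of association records.
#' @export
read_gwas_summary <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(snp_id = "character", gene = "character"))
  req <- c("snp_id", "chr", "pos", "effect_allele", "other_allele",
           "or", "pvalue", "strand", "gene")
  if (!all(req %in% names(x)))
    stop("summary table must have columns: ", paste(req, collapse = ", "))
  x
}

#' Harmonize an association catalog
#'
#' Applies, in order: (1) the genome-wide significance filter
#' (pvalue <= p_threshold); (2) strand correction — records reported on the
#' reverse strand have both alleles complemented and are set to forward;
#' strand-ambiguous pairs (A/T, C/G) on the reverse strand cannot be
#' oriented and are excluded unless `keep_ambiguous`; (3) effect-direction
#' orientation — records with odds ratio < 1 have effect and other allele
#' swapped and the odds ratio inverted, so every surviving record carries
#' the risk-increasing allele as effect allele with OR >= 1; (4) duplicate
#' snp_ids collapsed keeping the smallest p-value; (5) records with
#' non-ACGT alleles are rejected. Risk SNPs are the records with harmonized
#' odds ratio >= `or_floor`.
#'
#' @param records data.frame of association records (see
#'   [read_gwas_summary()] for columns).
#' @param p_threshold significance filter, default 5e-8.
#' @param or_floor odds-ratio floor defining risk SNPs, default 1.2.
#' @param keep_ambiguous keep reverse-strand strand-ambiguous records
#'   as-is instead of excluding them (default FALSE).
#' @return object of class `harmonized_catalog`: list with `records`
#'   (harmonized data.frame, logical column `is_risk`), `risk_subset`
#'   (rows with OR >= or_floor) and `exclusions` (data.frame snp_id,
#'   reason).
#' @export
harmonize <- function(records, p_threshold = 5e-8, or_floor = 1.2,
                      keep_ambiguous = FALSE) {
  req <- c("snp_id", "effect_allele", "other_allele", "or", "pvalue", "strand")
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  x <- as.data.frame(records)
  excl <- data.frame(snp_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  note <- function(ids, why) {
    if (length(ids)) rbind(excl, data.frame(snp_id = ids, reason = why,
                                            stringsAsFactors = FALSE)) else excl
  }

  bad_allele <- !(x$effect_allele %in% c("A", "C", "G", "T")) |
    !(x$other_allele %in% c("A", "C", "G", "T")) |
    x$effect_allele == x$other_allele
  excl <- note(x$snp_id[bad_allele], "non-ACGT or identical alleles")
  x <- x[!bad_allele, , drop = FALSE]

  drop_p <- x$pvalue > p_threshold
  excl <- note(x$snp_id[drop_p], "above p-value threshold")
  x <- x[!drop_p, , drop = FALSE]

  rev <- x$strand == "reverse"
  ambig <- is_strand_ambiguous(x$effect_allele, x$other_allele)
  if (!keep_ambiguous && any(rev & ambig)) {
    excl <- note(x$snp_id[rev & ambig], "strand-ambiguous on reverse strand")
    keep <- !(rev & ambig)
    x <- x[keep, , drop = FALSE]
    rev <- rev[keep]
  }
  if (any(rev)) {
    x$effect_allele[rev] <- complement_allele(x$effect_allele[rev])
    x$other_allele[rev] <- complement_allele(x$other_allele[rev])
    x$strand[rev] <- "forward"
  }

  flip <- x$or < 1
  if (any(flip)) {
    tmp <- x$effect_allele[flip]
    x$effect_allele[flip] <- x$other_allele[flip]
    x$other_allele[flip] <- tmp
    x$or[flip] <- 1 / x$or[flip]
  }

  if (anyDuplicated(x$snp_id)) {
    x <- x[order(x$snp_id, x$pvalue), , drop = FALSE]
    dup <- duplicated(x$snp_id)
    excl <- note(x$snp_id[dup], "duplicate snp_id (larger p-value)")
    x <- x[!dup, , drop = FALSE]
    x <- x[order(match(x$snp_id, records$snp_id)), , drop = FALSE]
  }

  if (nrow(x) == 0) stop("no records survive harmonization")
  x$is_risk <- x$or >= or_floor
  rownames(x) <- NULL
  structure(list(records = x, risk_subset = x[x$is_risk, , drop = FALSE],
                 exclusions = excl, p_threshold = p_threshold,
                 or_floor = or_floor),
            class = "harmonized_catalog")
}

#' @export
print.harmonized_catalog <- function(x, ...) {
  cat(sprintf("harmonized_catalog: %d records (%d risk SNPs, OR >= %.2f), %d excluded\n",
              nrow(x$records), nrow(x$risk_subset), x$or_floor, nrow(x$exclusions)))
  invisible(x)
}

#' Classify an allele-frequency spectrum
#'
#' Bins effect-allele frequencies into rare (< 1%), low-frequency
#' (1% <= f < 5%) and common (>= 5%); boundaries are half-open so 0.05 is
#' common and 0.01 is low-frequency.
#'
#' @param freqs numeric vector of frequencies in [0,1].
#' @return named integer vector with counts `rare`, `low_frequency`,
#'   `common`; sums to `length(freqs)`.
#' @export
classify_spectrum <- function(freqs) {
  if (any(freqs < 0 | freqs > 1, na.rm = TRUE) || anyNA(freqs))
    stop("frequencies must be in [0,1] and non-missing")
  c(rare = sum(freqs < 0.01),
    low_frequency = sum(freqs >= 0.01 & freqs < 0.05),
    common = sum(freqs >= 0.05))
}
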