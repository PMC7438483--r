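#' Genotype matrix container
#'
#' Bundles a samples x variants dosage matrix (counts of the alternate
#' allele, 0/1/2 or NA for missing) with variant metadata and a sample ->
#' population panel. This is the container every downstream stage
#' (frequencies, Fst, PCA, clumping, scoring) consumes.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   values in \{0, 1, 2, NA\}. Row names are sample ids, column names
#'   variant ids.
#' @param variants data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `ref`, `alt`; one row per matrix column, in column order.
#' @param panel data.frame with columns `sample_id`, `population`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, panel) {
  stopifnot(is.matrix(dosages))
  req <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants)))
    stop("variants must have columns: ", paste(req, collapse = ", "))
  if (nrow(variants) != ncol(dosages))
    stop("variants rows must match dosage columns")
  if (!all(c("sample_id", "population") %in% names(panel)))
    stop("panel must have sample_id and population columns")
  if (is.null(rownames(dosages))) rownames(dosages) <- panel$sample_id
  if (!all(panel$sample_id %in% rownames(dosages)))
    stop("every panel sample must appear in the dosage matrix")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  colnames(dosages) <- variants$snp_id
  structure(
    list(dosages = dosages, variants = as.data.frame(variants),
         panel = as.data.frame(panel)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants, %d population(s): %s\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$panel$population)),
              paste(sort(unique(x$panel$population)), collapse = ", ")))
  miss <- mean(is.na(x$dosages))
  if (miss > 0) cat(sprintf("  missing dosage rate: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param gm a [genotype_matrix()].
#' @param samples character vector of sample ids (default all).
#' @param snps character vector of snp ids (default all).
#' @return a `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(gm, samples = NULL, snps = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  rows <- if (is.null(samples)) rownames(gm$dosages) else samples
  cols <- if (is.null(snps)) gm$variants$snp_id else snps
  keep_v <- match(cols, gm$variants$snp_id)
  if (anyNA(keep_v)) stop("unknown snp ids: ", paste(cols[is.na(keep_v)], collapse = ", "))
  genotype_matrix(gm$dosages[rows, keep_v, drop = FALSE],
                  gm$variants[keep_v, , drop = FALSE],
                  gm$panel[gm$panel$sample_id %in% rows, , drop = FALSE])
}

#' Write a genotype matrix as a multi-sample VCF 4.2 file (GT field only)
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  samp <- rownames(gm$dosages)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=t2dburden",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samp), collapse = "\t"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(ncol(gm$dosages)), function(j) {
    d <- gm$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(v$chrom[j], v$pos[j], v$snp_id[j], v$ref[j], v$alt[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF (GT field) into a genotype matrix
#'
#' Parses biallelic SNP records of an uncompressed VCF. Multiallelic sites
#' are dropped with a warning (the whole analysis is biallelic). Genotypes
#' are collapsed to alternate-allele dosage; any missing allele makes the
#' dosage missing.
#'
#' @param vcf_path path to an uncompressed VCF file.
#' @param panel data.frame (`sample_id`, `population`) or path to a
#'   tab-separated panel file with those columns.
#' @return a [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(vcf_path, panel) {
  if (is.character(panel)) panel <- utils::read.delim(panel, stringsAsFactors = FALSE)
  lines <- readLines(vcf_path)
  hdr_i <- grep("^#CHROM", lines)
  if (length(hdr_i) != 1L) stop("not a VCF: missing #CHROM header line")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  samp <- hdr[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  alt <- vapply(fields, `[[`, "", 5L)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic site(s) dropped")
    fields <- fields[!multi]
  }
  n_var <- length(fields)
  variants <- data.frame(
    snp_id = vapply(fields, `[[`, "", 3L),
    chrom  = vapply(fields, `[[`, "", 1L),
    pos    = as.integer(vapply(fields, `[[`, "", 2L)),
    ref    = vapply(fields, `[[`, "", 4L),
    alt    = vapply(fields, `[[`, "", 5L),
    stringsAsFactors = FALSE)
  dos <- matrix(NA_real_, nrow = length(samp), ncol = n_var,
                dimnames = list(samp, variants$snp_id))
  for (j in seq_len(n_var)) {
    gt <- sub(":.*", "", fields[[j]][-(1:9)])
    a1 <- substr(gt, 1L, 1L)
    a2 <- substr(gt, 3L, 3L)
    d <- suppressWarnings(as.numeric(a1) + as.numeric(a2))
    dos[, j] <- d
  }
  genotype_matrix(dos, variants, panel)
}
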