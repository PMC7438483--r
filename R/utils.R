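#' @keywords internal
"_PACKAGE"

# Named substreams: every stochastic stage derives its own seed from the
# master seed so stages can be regenerated independently without replaying
# the whole stream.
substream_seed <- function(master_seed, stream) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 1009L)
  as.integer((as.numeric(master_seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Complement DNA alleles
#'
#' Maps each base to its Watson-Crick complement. Used when re-orienting
#' association records reported on the reverse strand.
#'
#' @param alleles character vector of single-base alleles (A/C/G/T).
#' @return character vector of complemented alleles.
#' @export
complement_allele <- function(alleles) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  if (!all(alleles %in% names(map)))
    stop("non-ACGT allele: ", paste(setdiff(alleles, names(map)), collapse = ", "))
  unname(map[alleles])
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
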