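# Independent oracle implementations, deliberately written as plain scalar
# code so they share nothing with the package's vectorized paths.

# Weir & Cockerham (1984) variance components for one locus, r populations,
# straight from the printed formulas, one number at a time.
wc_fst_oracle <- function(counts_list) {
  r <- length(counts_list)
  n <- sapply(counts_list, sum)
  p <- sapply(counts_list, function(cn) (cn[2] + 2 * cn[3]) / (2 * sum(cn)))
  h <- sapply(counts_list, function(cn) cn[2] / sum(cn))
  n_bar <- mean(n)
  n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n * p) / (r * n_bar)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / (r * n_bar)
  a <- (n_bar / n_c) * (s2 - 1 / (n_bar - 1) *
                          (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
                                  (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  list(a = a, b = b, c = cc,
       theta = if ((a + b + cc) == 0) NA_real_ else a / (a + b + cc))
}

# Benjamini-Hochberg by the literal step-up definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[o[i]] <- min(1, min(p[o[js]] * m / js))
  }
  q
}

# Greedy clumping re-enumerated independently: explicit while-loop over a
# working copy of the summary table.
clump_oracle <- function(summary, dosages, r2_threshold, window_bp) {
  s <- summary[order(summary$pvalue, summary$pos, summary$snp_id), ]
  kept <- character(0)
  while (nrow(s) > 0) {
    idx <- s[1, ]
    kept <- c(kept, idx$snp_id)
    s <- s[-1, , drop = FALSE]
    if (nrow(s) == 0) break
    drop <- logical(nrow(s))
    for (k in seq_len(nrow(s))) {
      if (s$chrom[k] != idx$chrom) next
      if (abs(s$pos[k] - idx$pos) > window_bp) next
      r <- suppressWarnings(cor(dosages[, idx$snp_id], dosages[, s$snp_id[k]],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_threshold) drop[k] <- TRUE
    }
    s <- s[!drop, , drop = FALSE]
  }
  sort(kept)
}

# Poisson regression (log link) by hand-rolled IRLS on the normal equations.
poisson_irls_oracle <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) + 1e-9)
  for (it in seq_len(maxit)) {
    mu <- exp(as.numeric(X %*% beta))
    W <- mu
    z <- as.numeric(X %*% beta) + (y - mu) / mu
    beta_new <- solve(t(X) %*% (X * W), t(X) %*% (W * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.numeric(beta)
}

# Small genotype-matrix fixture built directly from a dosage matrix.
make_gm <- function(dosages, populations = NULL, chrom = NULL, pos = NULL,
                    ref = NULL, alt = NULL) {
  n <- nrow(dosages); m <- ncol(dosages)
  ids <- sprintf("s%03d", seq_len(n))
  snps <- colnames(dosages) %||% sprintf("snp%03d", seq_len(m))
  rownames(dosages) <- ids
  genotype_matrix(
    dosages,
    data.frame(snp_id = snps,
               chrom = chrom %||% rep("1", m),
               pos = pos %||% (seq_len(m) * 1000L),
               ref = ref %||% rep("A", m),
               alt = alt %||% rep("G", m),
               stringsAsFactors = FALSE),
    data.frame(sample_id = ids,
               population = populations %||% rep("P1", n),
               stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random genotype-count configurations for the Fst oracle sweep.
random_count_pair <- function() {
  repeat {
    c1 <- c(sample(0:30, 1), sample(0:30, 1), sample(0:30, 1))
    c2 <- c(sample(0:30, 1), sample(0:30, 1), sample(0:30, 1))
    if (sum(c1) >= 2 && sum(c2) >= 2) return(list(c1 = c1, c2 = c2))
  }
}
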