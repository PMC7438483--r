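test_that("wc_fst matches trivial cases and is symmetric", {
  # fixed difference: theta = 1 exactly
  r <- wc_fst(c(0, 0, 10), c(10, 0, 0))
  expect_identical(r$theta, 1)
  # identical genotype counts: between-population component non-positive
  r2 <- wc_fst(c(5, 5, 5), c(5, 5, 5))
  expect_lte(r2$theta, 0)
  # symmetry in population order
  r3a <- wc_fst(c(2, 2, 1), c(4, 1, 0))
  r3b <- wc_fst(c(4, 1, 0), c(2, 2, 1))
  expect_equal(r3a$theta, r3b$theta, tolerance = 1e-15)
  # both monomorphic for the same allele: undefined, not a crash
  r4 <- wc_fst(c(10, 0, 0), c(5, 0, 0))
  expect_true(r4$undefined)
  expect_true(is.na(r4$theta))
  # < 2 samples: per-SNP undefined flag
  r5 <- wc_fst(c(1, 0, 0), c(3, 3, 3))
  expect_true(r5$undefined)
})

test_that("wc_fst equals the independently coded 1984 oracle", {
  got <- wc_fst(c(2, 2, 1), c(4, 1, 0))
  exp <- wc_fst_oracle(list(c(2, 2, 1), c(4, 1, 0)))
  expect_equal(got$theta, exp$theta, tolerance = 1e-12)
  expect_equal(got$a, exp$a, tolerance = 1e-12)
  expect_equal(got$b, exp$b, tolerance = 1e-12)
  expect_equal(got$c, exp$c, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:100) {
    cp <- random_count_pair()
    got <- wc_fst(cp$c1, cp$c2)
    exp <- wc_fst_oracle(list(cp$c1, cp$c2))
    if (is.na(exp$theta)) expect_true(is.na(got$theta))
    else expect_lt(abs(got$theta - exp$theta), 1e-12)
  }
})

test_that("mean_fst averages defined estimates and reports ratio-of-sums", {
  expect_equal(mean_fst(c(0.1, 0.3))$mean_theta, 0.2)
  expect_equal(mean_fst(0.07)$mean_theta, 0.07)
  expect_error(mean_fst(c(NA_real_, NA_real_)), "no defined")
  set.seed(9)
  cl <- replicate(100, random_count_pair(), simplify = FALSE)
  res <- wc_fst(do.call(rbind, lapply(cl, `[[`, "c1")),
                do.call(rbind, lapply(cl, `[[`, "c2")))
  m <- mean_fst(res)
  expect_equal(m$mean_theta, mean(res$theta[!res$undefined]))
  ok <- !res$undefined
  expect_equal(m$ratio_of_sums,
               sum(res$a[ok]) / sum(res$a[ok] + res$b[ok] + res$c[ok]))
})

test_that("frequency-matched sampling respects bins and matches histograms", {
  target <- setNames(runif(50, 0.4, 0.42), paste0("t", 1:50))
  # pool = target (renamed): result is a permutation of the pool
  pool <- setNames(target, paste0("p", 1:50))
  got <- sample_frequency_matched(target, pool, seed = 1)
  expect_setequal(got, names(pool))
  # constrained pool: only same-bin SNPs are drawn
  target2 <- setNames(rep(0.5, 20), paste0("t", 1:20))
  pool2 <- setNames(c(rep(0.5, 30), rep(0.05, 30)), paste0("p", 1:60))
  got2 <- sample_frequency_matched(target2, pool2, bin_width = 0.02, seed = 2)
  expect_true(all(pool2[got2] == 0.5))
  # per-bin counts equal per-bin counts of the target exactly
  set.seed(3)
  target3 <- setNames(runif(1000), paste0("t", 1:1000))
  pool3 <- setNames(runif(20000), paste0("p", 1:20000))
  got3 <- sample_frequency_matched(target3, pool3, bin_width = 0.02, seed = 4)
  expect_equal(length(got3), 1000L)
  bins <- function(f) table(factor(floor(f / 0.02), levels = 0:50))
  expect_equal(as.integer(bins(pool3[got3])), as.integer(bins(target3)))
  # KS distance between matched and target distributions <= bin width
  expect_lt(suppressWarnings(
    ks.test(target3, pool3[got3])$statistic), 0.02 + 1e-9)
})

test_that("high_fst_selection_test counts and chi-square follow the rules", {
  x <- c(runif(100, 0, 0.04), runif(10, 0.2, 0.5))
  sel <- high_fst_selection_test(x, x)
  expect_equal(sel$chi2, 0)
  expect_equal(sel$pvalue, 1)
  expect_equal(sel$n_high_t2d, sel$n_high_random)
  expect_error(high_fst_selection_test(x, x[-1]), "mismatch")
  # the high-Fst definition is floor AND pooled top-quantile
  y <- c(rep(0.2, 2), rep(0.01, 98))
  sel2 <- high_fst_selection_test(y, rep(0.01, 100), top_quantile = 0.01)
  expect_equal(sel2$n_high_t2d, 2L)
  expect_equal(sel2$n_high_random, 0L)
  # chi-square equals the hand Pearson formula on the printed-style table
  tab <- matrix(c(109, 2302 - 109, 120, 2302 - 120), 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chisq_2x2(tab)$statistic, sum((tab - e)^2 / e))
  expect_equal(chisq_2x2(tab)$statistic,
               unname(chisq.test(tab, correct = FALSE)$statistic))
})

test_that("genotype_pca separates structured populations and is sane", {
  cfg <- sim_config(n_snps = 300, n_catalog_snps = 100, n_risk_snps = 20,
                    ld_block_size = 1,
                    populations = list(population_spec("P1", 100, 0.1),
                                       population_spec("P2", 100, 0.1)),
                    seed = 12)
  fr <- simulate_frequency_table(cfg)
  gm <- simulate_genotypes(fr$pop_freqs, cfg)
  pc <- genotype_pca(gm, n_components = 4)
  s1 <- pc$scores[pc$populations == "P1", 1]
  s2 <- pc$scores[pc$populations == "P2", 1]
  pooled_sd <- sqrt((var(s1) + var(s2)) / 2)
  expect_gt(abs(mean(s1) - mean(s2)), 3 * pooled_sd)
  # scores orthogonal; explained fractions sum <= 1
  g <- crossprod(pc$scores)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
  expect_lte(sum(pc$explained), 1 + 1e-12)
  # duplicated samples get identical scores
  gm2 <- make_gm(rbind(gm$dosages[1:20, ], gm$dosages[1:20, ]),
                 populations = rep("P", 40))
  pc2 <- genotype_pca(gm2, n_components = 2)
  expect_equal(unname(pc2$scores[1:20, ]), unname(pc2$scores[21:40, ]),
               tolerance = 1e-8)
  # all-monomorphic input errors
  expect_error(genotype_pca(make_gm(matrix(2, 10, 3))), "polymorphic")
})

test_that("mean Fst increases with Balding-Nichols divergence (seeded)", {
  ms <- vapply(c(0.01, 0.05, 0.1, 0.2), function(cc) {
    cfg <- sim_config(n_snps = 400, n_catalog_snps = 100, n_risk_snps = 20,
                      ld_block_size = 1,
                      populations = list(population_spec("P1", 150, cc),
                                         population_spec("P2", 150, cc)),
                      seed = 77)
    fr <- simulate_frequency_table(cfg)
    gm <- simulate_genotypes(fr$pop_freqs, cfg)
    mean_fst(fst_pairwise(gm))$mean_theta
  }, numeric(1))
  expect_true(all(diff(ms) > 0))
  # frozen pilot mapping: realized mean ~= 0.47 * 2c/(1+c) within 25%
  pred <- 0.47 * 2 * c(0.01, 0.05, 0.1, 0.2) / (1 + c(0.01, 0.05, 0.1, 0.2))
  expect_true(all(abs(ms - pred) / pred < 0.25))
})
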