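sim_cohort <- function(n = 4000, prevalence_beta = log(1.5) / 2.8016,
                       hazard_beta = log(2) / 2.8016, seed = 1,
                       n_snps = 120) {
  cfg <- sim_config(n_snps = n_snps, n_catalog_snps = n_snps,
                    n_risk_snps = min(60, n_snps), ld_block_size = 1,
                    prevalence_beta = prevalence_beta,
                    hazard_beta = hazard_beta,
                    populations = list(population_spec("IR", n, 0.02)),
                    seed = seed)
  fr <- simulate_frequency_table(cfg)
  gm <- simulate_genotypes(fr$pop_freqs, cfg)
  gwas <- simulate_gwas_table(gm$variants, cfg)
  ph <- simulate_phenotypes(gm, attr(gwas, "risk_weights"), cfg)
  build_cohort(ph, data.frame(sample_id = ph$sample_id,
                              score = ph$true_score, n_snps_used = 1))
}

test_that("prevalence_ratios matches an independent IRLS fit on a fixture", {
  set.seed(7)
  n <- 50
  cohort <- data.frame(
    sample_id = as.character(1:n),
    prevalent_t2d = rbinom(n, 1, 0.3),
    quintile = sample(1:5, n, replace = TRUE),
    age = rnorm(n, 45, 10), sex = rbinom(n, 1, 0.5), bmi = rnorm(n, 27, 4))
  pr <- prevalence_ratios(cohort)
  X <- model.matrix(~ factor(quintile) + age + sex + bmi, cohort)
  beta <- poisson_irls_oracle(X, cohort$prevalent_t2d)
  expect_equal(log(pr$estimate), beta[2:5], tolerance = 1e-6,
               ignore_attr = TRUE)
  # robust sandwich SEs are used, not the model-based ones
  fit <- glm(prevalent_t2d ~ factor(quintile) + age + sex + bmi,
             data = cohort, family = poisson())
  mu <- fit$fitted.values
  Xf <- model.matrix(fit)
  bread <- solve(t(Xf) %*% (Xf * mu))
  meat <- t(Xf) %*% (Xf * (fit$y - mu)^2)
  se_hc0 <- sqrt(diag(bread %*% meat %*% bread))[2:5]
  expect_equal((log(pr$ci_high) - log(pr$estimate)) / 1.96, se_hc0,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("prevalence_ratios recovers null and a true PR of 1.5", {
  null_cohort <- sim_cohort(n = 5000, prevalence_beta = 0, hazard_beta = 0,
                            seed = 3)
  pr0 <- prevalence_ratios(null_cohort)
  expect_true(all(pr0$ci_low <= 1 & pr0$ci_high >= 1))
  cohort <- sim_cohort(n = 10000, seed = 5)
  pr <- prevalence_ratios(cohort)
  q5 <- pr$estimate[pr$contrast == "Q5 vs Q1"]
  expect_gt(q5, 1.35)
  expect_lt(q5, 1.65)
})

test_that("hazard_ratios matches a hand-coded partial likelihood root", {
  # four subjects, distinct times, binary covariate, no ties
  cohort <- data.frame(
    sample_id = as.character(1:4), prevalent_t2d = 0,
    time_years = c(1, 2, 3, 4), event = c(1, 1, 1, 0),
    quintile = c(5, 1, 5, 1))
  # score equation solved independently on the explicit risk sets
  x <- c(1, 0, 1, 0)
  score_eq <- function(b) {
    (x[1] - sum(x * exp(b * x)) / sum(exp(b * x))) +
      (x[2] - sum(x[2:4] * exp(b * x[2:4])) / sum(exp(b * x[2:4]))) +
      (x[3] - sum(x[3:4] * exp(b * x[3:4])) / sum(exp(b * x[3:4])))
  }
  root <- uniroot(score_eq, c(-5, 5), tol = 1e-12)$root
  hr <- hazard_ratios(cohort, covariates = character(0))
  expect_equal(log(hr$estimate[hr$contrast == "Q5 vs Q1"]), root,
               tolerance = 1e-6)
})

test_that("hazard_ratios recovers null and a true HR of 2", {
  null_cohort <- sim_cohort(n = 5000, prevalence_beta = 0, hazard_beta = 0,
                            seed = 11)
  hr0 <- hazard_ratios(null_cohort)
  expect_true(hr0$ci_low[4] <= 1 && hr0$ci_high[4] >= 1)
  # average over three replicate cohorts to tame quintile-contrast noise
  lhr <- vapply(1:3, function(s) {
    log(hazard_ratios(sim_cohort(n = 10000, seed = 100 + s))$estimate[4])
  }, numeric(1))
  expect_gt(exp(mean(lhr)), 1.7)
  expect_lt(exp(mean(lhr)), 2.3)
})

test_that("hazard_ratios flags non-identifiable quintiles and bad input", {
  cohort <- sim_cohort(n = 1000, seed = 13)
  # zero events in quintile 3
  cohort$event[cohort$quintile == 3 & !is.na(cohort$event)] <- 0
  hr <- suppressWarnings(hazard_ratios(cohort))
  expect_true(hr$non_identifiable[hr$contrast == "Q3 vs Q1"])
  cohort2 <- cohort
  cohort2$event[!is.na(cohort2$event)] <- 0
  expect_error(hazard_ratios(cohort2), "no incident events")
})

test_that("cumulative_incidence equals hand-computed product-limit values", {
  cohort <- data.frame(
    sample_id = as.character(1:6), prevalent_t2d = 0,
    time_years = c(1, 2, 2, 3, 4, 5), event = c(1, 0, 1, 1, 0, 1),
    category = "all")
  ci <- cumulative_incidence(cohort, grouping = "category")
  # hand KM: S(1)=5/6, S(2)=5/6*4/5, S(3)=2/3*2/3, S(5)=0
  expect_equal(ci$cum_inc[ci$time == 1], 1 - 5 / 6, tolerance = 1e-12)
  expect_equal(ci$cum_inc[ci$time == 2], 1 - 5 / 6 * 4 / 5, tolerance = 1e-12)
  expect_equal(ci$cum_inc[ci$time == 3], 1 - 5 / 6 * 4 / 5 * 2 / 3,
               tolerance = 1e-12)
  expect_equal(ci$cum_inc[ci$time == 5], 1, tolerance = 1e-12)
  expect_true(all(diff(ci$cum_inc) >= 0))
  # without censoring the curve is the empirical CDF
  cohort2 <- data.frame(sample_id = as.character(1:5), prevalent_t2d = 0,
                        time_years = 1:5, event = 1, category = "all")
  ci2 <- cumulative_incidence(cohort2, grouping = "category")
  expect_equal(ci2$cum_inc, (1:5) / 5, tolerance = 1e-12)
  # no events: flat zero
  cohort3 <- cohort2
  cohort3$event <- 0
  expect_true(all(cumulative_incidence(cohort3, "category")$cum_inc == 0))
})

test_that("biomarker_associations equals the normal-equations oracle", {
  set.seed(19)
  n <- 30
  cohort <- data.frame(
    sample_id = as.character(1:n), prevalent_t2d = 0,
    quintile = sample(1:5, n, replace = TRUE),
    age = rnorm(n, 45, 10), sex = rbinom(n, 1, 0.5), bmi = rnorm(n, 27, 4),
    fpg = rnorm(n, 90, 9), g2h = rnorm(n, 100, 20), tc = rnorm(n, 200, 40),
    tg = rnorm(n, 150, 70), hdl = rnorm(n, 41, 9), ldl = rnorm(n, 128, 30))
  ba <- biomarker_associations(cohort, "fpg")
  X <- model.matrix(~ factor(quintile) + age + sex + bmi + g2h + tc + tg +
                      hdl + ldl, cohort)
  beta <- solve(t(X) %*% X, t(X) %*% cohort$fpg)
  expect_equal(ba$estimate, beta[2:5], tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(biomarker_associations(cohort, "height"), "unknown biomarker")
})

test_that("a planted fasting-glucose shift in quintile 5 is recovered", {
  cohort <- sim_cohort(n = 10000, prevalence_beta = 0, hazard_beta = 0,
                       seed = 29)
  cohort$fpg <- cohort$fpg + 3 * (cohort$quintile == 5)
  ba <- biomarker_associations(cohort, "fpg")
  q5 <- ba$estimate[ba$contrast == "Q5 vs Q1"]
  expect_gt(q5, 2)
  expect_lt(q5, 4)
  # null quintiles 2-4 cover zero
  expect_true(all(ba$ci_low[1:3] <= 0 & ba$ci_high[1:3] >= 0))
})

test_that("estimates are invariant to sample relabeling", {
  cohort <- sim_cohort(n = 2000, seed = 31)
  perm <- cohort[sample(nrow(cohort)), ]
  pr1 <- prevalence_ratios(cohort)
  pr2 <- prevalence_ratios(perm)
  expect_equal(pr1$estimate, pr2$estimate, tolerance = 1e-10)
  hr1 <- hazard_ratios(cohort)
  hr2 <- hazard_ratios(perm)
  expect_equal(hr1$estimate, hr2$estimate, tolerance = 1e-8)
})
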