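#' Assemble the analysis cohort table
#'
#' Merges per-sample phenotypes with polygenic scores and attaches score
#' quintiles and genetic-risk categories.
#'
#' @param phenotypes data.frame from [simulate_phenotypes()] or read from
#'   the phenotype CSV (sample_id, sex, age, bmi, fpg, g2h, tc, tg, hdl,
#'   ldl, prevalent_t2d, time_years, event).
#' @param prs a `prs_result` from [compute_prs()].
#' @return data.frame (class `cohort_table`) with score, quintile and
#'   category columns appended.
#' @export
build_cohort <- function(phenotypes, prs) {
  x <- merge(as.data.frame(phenotypes), as.data.frame(prs), by = "sample_id")
  q <- assign_quintiles(x$score)
  x$quintile <- q$quintile
  x$category <- q$category
  class(x) <- c("cohort_table", "data.frame")
  x
}

wald_rows <- function(coef, se, labels, measure, exponentiate = TRUE) {
  z <- coef / se
  p <- 2 * stats::pnorm(-abs(z))
  est <- if (exponentiate) exp(coef) else coef
  lo <- if (exponentiate) exp(coef - 1.96 * se) else coef - 1.96 * se
  hi <- if (exponentiate) exp(coef + 1.96 * se) else coef + 1.96 * se
  data.frame(contrast = labels, measure = measure, estimate = est,
             ci_low = lo, ci_high = hi, pvalue = p,
             stringsAsFactors = FALSE)
}

#' Prevalence ratios of disease by score quintile (robust Poisson)
#'
#' Fits a log-link Poisson model of prevalent status on quintile
#' indicators plus covariates and reports exponentiated coefficients as
#' prevalence ratios with HC0 sandwich (robust) standard errors — the
#' standard modified-Poisson approach for binary outcomes when the
#' prevalence is too high for odds ratios to approximate risks.
#'
#' @param cohort a cohort table with prevalent_t2d and quintile columns.
#' @param covariates covariate column names (default age, sex, bmi; use
#'   character(0) for the unadjusted model).
#' @return data.frame of effect estimates for quintiles 2-5 vs 1
#'   (contrast, measure = "PR", estimate, ci_low, ci_high, pvalue), with
#'   attribute `n` = samples used.
#' @export
prevalence_ratios <- function(cohort, covariates = c("age", "sex", "bmi")) {
  if (!1 %in% cohort$quintile) stop("reference quintile 1 absent")
  dat <- cohort[stats::complete.cases(
    cohort[, c("prevalent_t2d", "quintile", covariates), drop = FALSE]), ]
  fml <- stats::reformulate(c("factor(quintile)", covariates),
                            response = "prevalent_t2d")
  fit <- stats::glm(fml, data = dat, family = stats::poisson())
  if (!fit$converged) stop("Poisson fit did not converge; check separation")
  X <- stats::model.matrix(fit)
  mu <- fit$fitted.values
  y <- fit$y
  bread <- solve(crossprod(X, X * mu))
  meat <- crossprod(X, X * (y - mu)^2)
  V <- bread %*% meat %*% bread
  se <- sqrt(diag(V))
  keep <- grep("^factor\\(quintile\\)", names(stats::coef(fit)))
  out <- wald_rows(stats::coef(fit)[keep], se[keep],
                   paste0("Q", sub("factor\\(quintile\\)", "",
                                   names(stats::coef(fit))[keep]), " vs Q1"),
                   "PR")
  attr(out, "n") <- nrow(dat)
  attr(out, "fit") <- fit
  out
}

#' Hazard ratios of incident disease by score quintile (Cox regression)
#'
#' Fits a proportional-hazards model (Efron tie handling) of incident
#' disease on quintile indicators plus covariates, on the baseline-free
#' subcohort (prevalent cases removed). Supports both the age/sex/BMI
#' model and the full model additionally adjusted for the six biomarkers.
#'
#' @param cohort a cohort table with time_years, event, prevalent_t2d.
#' @param covariates covariate names; use
#'   `c("age","sex","bmi","fpg","g2h","tc","tg","hdl","ldl")` for the
#'   full model.
#' @return data.frame of effect estimates for quintiles 2-5 vs 1
#'   (measure = "HR") with a logical `non_identifiable` column flagging
#'   quintiles with zero events; attributes `n` and `n_events`.
#' @export
hazard_ratios <- function(cohort, covariates = c("age", "sex", "bmi")) {
  dat <- cohort[cohort$prevalent_t2d == 0, , drop = FALSE]
  dat <- dat[stats::complete.cases(
    dat[, c("time_years", "event", "quintile", covariates), drop = FALSE]), ]
  if (any(dat$time_years <= 0)) stop("non-positive follow-up time")
  if (sum(dat$event) < 1) stop("no incident events")
  fml <- stats::reformulate(c("factor(quintile)", covariates),
                            response = "survival::Surv(time_years, event)")
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  keep <- grep("^factor\\(quintile\\)", names(stats::coef(fit)))
  se <- sqrt(diag(fit$var))[keep]
  out <- wald_rows(stats::coef(fit)[keep], se,
                   paste0("Q", sub("factor\\(quintile\\)", "",
                                   names(stats::coef(fit))[keep]), " vs Q1"),
                   "HR")
  ev <- tapply(dat$event, dat$quintile, sum)
  qs <- as.integer(sub("Q(\\d+) vs Q1", "\\1", out$contrast))
  out$non_identifiable <- is.na(ev[as.character(qs)]) | ev[as.character(qs)] == 0
  attr(out, "n") <- nrow(dat)
  attr(out, "n_events") <- sum(dat$event)
  attr(out, "fit") <- fit
  out
}

#' Cumulative incidence curves by genetic-risk category
#'
#' 1 - Kaplan-Meier estimate per category on the baseline-free subcohort;
#' curves are non-decreasing step functions respecting right censoring.
#'
#' @param cohort a cohort table.
#' @param grouping grouping column, default "category".
#' @return data.frame with group, time, cum_inc, n_risk, n_event.
#' @export
cumulative_incidence <- function(cohort, grouping = "category") {
  dat <- cohort[cohort$prevalent_t2d == 0 & !is.na(cohort$time_years), ,
                drop = FALSE]
  groups <- unique(as.character(dat[[grouping]]))
  empty <- setdiff(unique(as.character(cohort[[grouping]])), groups)
  if (length(empty))
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(groups, function(g) {
    d <- dat[dat[[grouping]] == g, ]
    sf <- survival::survfit(survival::Surv(time_years, event) ~ 1, data = d)
    data.frame(group = g, time = sf$time, cum_inc = 1 - sf$surv,
               n_risk = sf$n.risk, n_event = sf$n.event,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Linear association of a biomarker with score quintile
#'
#' Ordinary least squares of the biomarker on quintile indicators plus
#' age, sex, BMI and the remaining biomarkers, on individuals free of
#' prevalent disease. The dependent biomarker is excluded from the
#' adjustment set.
#'
#' @param cohort a cohort table.
#' @param biomarker one of "fpg", "g2h", "tc", "tg", "hdl", "ldl".
#' @return data.frame of effect estimates (measure = "beta", identity
#'   scale) for quintiles 2-5 vs 1.
#' @export
biomarker_associations <- function(cohort, biomarker) {
  markers <- c("fpg", "g2h", "tc", "tg", "hdl", "ldl")
  if (!biomarker %in% markers) stop("unknown biomarker: ", biomarker)
  dat <- cohort[cohort$prevalent_t2d == 0, , drop = FALSE]
  if (stats::var(dat[[biomarker]], na.rm = TRUE) == 0)
    stop("degenerate biomarker: zero variance")
  adj <- c("age", "sex", "bmi", setdiff(markers, biomarker))
  fml <- stats::reformulate(c("factor(quintile)", adj), response = biomarker)
  fit <- stats::lm(fml, data = dat)
  if (fit$rank < ncol(stats::model.matrix(fit)))
    stop("collinear design: rank-deficient model matrix")
  sm <- summary(fit)$coefficients
  keep <- grep("^factor\\(quintile\\)", rownames(sm))
  out <- wald_rows(sm[keep, 1], sm[keep, 2],
                   paste0("Q", sub("factor\\(quintile\\)", "",
                                   rownames(sm)[keep]), " vs Q1"),
                   "beta", exponentiate = FALSE)
  attr(out, "n") <- length(fit$residuals)
  out
}
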