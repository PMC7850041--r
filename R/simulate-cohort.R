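#' Simulate a cohort covariate table
#'
#' Draws per-subject demographic and coverage covariates from fixed marginal
#' distributions and assigns a binary case/control group label from a
#' logistic model on those covariates with user-supplied coefficients. The
#' generating coefficients are retained so propensity-model recovery can be
#' checked against ground truth.
#'
#' Covariates mirror those used for cohort construction: sex, handedness,
#' prior resection, years of education, age at seizure onset, and per-region
#' electrode-coverage and seizure-onset-zone indicators (4-region set), plus
#' age.
#'
#' @param n_total Total number of subjects; at least 8 (matching is undefined
#'   below that).
#' @param coefficients Named numeric vector of logistic coefficients on the
#'   standardised covariates. Unnamed entries are an error; covariates not
#'   named get coefficient 0. The name `"(Intercept)"` sets the intercept
#'   (default `qlogis(0.25)`, i.e. ~25% cases).
#' @param rng_seed Integer seed.
#' @return A tibble of class `cohort_table` with one row per subject.
#' @export
#' @examples
#' simulate_cohort(40, c("(Intercept)" = -1.1, age = 0.8), rng_seed = 7)
simulate_cohort <- function(n_total, coefficients = numeric(), rng_seed) {
  if (n_total < 8) abort("n_total must be at least 8 for matching to be defined.")
  if (length(coefficients) > 0 && is.null(names(coefficients))) {
    abort("coefficients must be a named vector.")
  }
  set.seed(as.integer(rng_seed))
  n <- as.integer(n_total)
  regions <- c("frontal", "MTL", "LTC", "parietal")
  cov <- tibble(
    subject = sprintf("sub%04d", seq_len(n)),
    age = pmin(pmax(round(rnorm(n, 38, 12)), 18), 70),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.55, 0.45)),
    handedness = sample(c("R", "L", "A"), n, replace = TRUE, prob = c(0.80, 0.15, 0.05)),
    prior_resection = runif(n) < 0.12,
    education_years = pmin(pmax(round(rnorm(n, 13, 2.5)), 6), 20)
  )
  cov$seizure_onset_age <- pmin(pmax(round(rnorm(n, 18, 10)), 1), cov$age)
  for (r in regions) {
    cov[[paste0("coverage_", r)]] <- runif(n) < 0.6
    cov[[paste0("soz_", r)]] <- runif(n) < 0.25
  }

  x <- cohort_design_matrix(cov)
  beta <- setNames(rep(0, ncol(x)), colnames(x))
  intercept <- qlogis(0.25)
  for (nm in names(coefficients)) {
    if (nm == "(Intercept)") {
      intercept <- coefficients[[nm]]
    } else if (nm %in% colnames(x)) {
      beta[nm] <- coefficients[[nm]]
    } else {
      abort(sprintf("Unknown covariate '%s' in coefficients.", nm))
    }
  }
  eta <- intercept + drop(x %*% beta)
  cov$group <- ifelse(runif(n) < plogis(eta), "case", "control")
  attr(cov, "truth_coefficients") <- c("(Intercept)" = intercept, beta)
  class(cov) <- c("cohort_table", class(cov))
  cov
}

# Standardised numeric design matrix used both to generate group labels and
# as the target parameterisation for coefficient-recovery tests.
cohort_design_matrix <- function(cohort) {
  regions <- c("frontal", "MTL", "LTC", "parietal")
  zscale <- function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  cols <- list(
    age = zscale(cohort$age),
    sex_male = as.numeric(cohort$sex == "M"),
    hand_left = as.numeric(cohort$handedness == "L"),
    hand_ambi = as.numeric(cohort$handedness == "A"),
    prior_resection = as.numeric(cohort$prior_resection),
    education_years = zscale(cohort$education_years),
    seizure_onset_age = zscale(cohort$seizure_onset_age)
  )
  for (r in regions) {
    cols[[paste0("coverage_", r)]] <- as.numeric(cohort[[paste0("coverage_", r)]])
    cols[[paste0("soz_", r)]] <- as.numeric(cohort[[paste0("soz_", r)]])
  }
  do.call(cbind, cols)
}
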