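#' Covariates used by the propensity model
#'
#' @return Character vector of the cohort-table covariate columns entering
#'   [fit_propensity()] and [balance_table()].
#' @export
propensity_covariates <- function() {
  regions <- c("frontal", "MTL", "LTC", "parietal")
  c(
    "age", "sex", "handedness", "prior_resection", "education_years",
    "seizure_onset_age",
    paste0("coverage_", regions), paste0("soz_", regions)
  )
}

#' Fit a propensity model for case membership
#'
#' Logistic generalized linear model of case (vs control) membership on the
#' cohort covariates; the fitted probability of being a case is each
#' subject's propensity score.
#'
#' @param cohort Cohort tibble with a `group` column (`"case"`/`"control"`)
#'   and the covariate columns (see [propensity_covariates()]).
#' @param covariates Covariate column names; defaults to every propensity
#'   covariate present in `cohort`.
#' @return `cohort` with a `propensity` column added, carrying the fitted
#'   `glm` as attribute `propensity_model` and a `separation` flag when
#'   fitted probabilities hit 0/1 numerically.
#' @export
fit_propensity <- function(cohort, covariates = NULL) {
  if (!all(c("subject", "group") %in% names(cohort))) {
    abort("Cohort table needs 'subject' and 'group' columns.")
  }
  if (length(unique(cohort$group)) != 2) {
    abort("Both groups must be present to fit a propensity model.")
  }
  covariates <- covariates %||% intersect(propensity_covariates(), names(cohort))
  if (length(covariates) == 0) abort("No covariate columns found.")
  if (anyNA(cohort[covariates])) abort("Covariates must be complete.")
  constant <- vapply(covariates, function(cv) length(unique(cohort[[cv]])) < 2, logical(1))
  if (any(constant)) {
    inform(paste0(
      "Constant covariate(s) dropped from the propensity model: ",
      paste(covariates[constant], collapse = ", ")
    ))
    covariates <- covariates[!constant]
  }
  rhs <- if (length(covariates) == 0) "1" else paste(covariates, collapse = " + ")
  f <- as.formula(paste("I(group == \"case\") ~", rhs))
  model <- glm(f, data = cohort, family = binomial())
  p <- unname(predict(model, type = "response"))
  eps <- 1e-8
  if (any(p < eps | p > 1 - eps)) {
    warn("Fitted propensities at the 0/1 boundary; possible separation.")
    attr(model, "separation") <- TRUE
  }
  cohort$propensity <- p
  attr(cohort, "propensity_model") <- model
  cohort
}

#' Match controls to cases on propensity, exact on handedness
#'
#' Greedy nearest-neighbour matching without replacement: cases are
#' processed in descending propensity order and each receives its
#' `match_ratio` nearest-propensity controls (distance on the probability
#' scale, or the logit scale) among the still-unmatched controls with
#' identical handedness. Distance ties break by subject id order, so
#' matching is deterministic. Cases that cannot be fully matched are
#' reported.
#'
#' @param cohort Cohort tibble with `propensity` (see [fit_propensity()]),
#'   `group`, `handedness`.
#' @param match_ratio Controls per case (default 3).
#' @param distance `"probability"` or `"logit"` scale for |delta propensity|.
#' @return An object of class `cohort_match`: list with `matched` (the
#'   cohort restricted to cases and their matched controls, controls carrying
#'   `matched_to`), `unmatched_cases` (tibble `subject`,
#'   `n_controls_found`), the full `cohort`, and `match_ratio`.
#' @export
match_controls <- function(cohort, match_ratio = 3,
                           distance = c("probability", "logit")) {
  distance <- match.arg(distance)
  if (!"propensity" %in% names(cohort)) {
    abort("Run fit_propensity() first: no 'propensity' column.")
  }
  score <- if (distance == "logit") qlogis(cohort$propensity) else cohort$propensity
  cases <- cohort |>
    mutate(.score = score) |>
    filter(.data$group == "case") |>
    arrange(desc(.data$propensity), .data$subject)
  controls <- cohort |>
    mutate(.score = score) |>
    filter(.data$group == "control")
  if (nrow(cases) == 0 || nrow(controls) == 0) {
    abort("Matching needs both cases and controls.")
  }
  available <- rep(TRUE, nrow(controls))
  assignment <- rep(NA_character_, nrow(controls))
  short <- list()
  for (i in seq_len(nrow(cases))) {
    cand <- which(available & controls$handedness == cases$handedness[i])
    if (length(cand) == 0) {
      short[[length(short) + 1]] <- tibble(
        subject = cases$subject[i], n_controls_found = 0L
      )
      next
    }
    d <- abs(controls$.score[cand] - cases$.score[i])
    ord <- cand[order(d, controls$subject[cand])]
    take <- head(ord, match_ratio)
    assignment[take] <- cases$subject[i]
    available[take] <- FALSE
    if (length(take) < match_ratio) {
      short[[length(short) + 1]] <- tibble(
        subject = cases$subject[i], n_controls_found = length(take)
      )
    }
  }
  unmatched <- list_rbind(short)
  if (nrow(unmatched) > 0) {
    warn(sprintf(
      "%d case(s) matched with fewer than %d handedness-compatible controls.",
      nrow(unmatched), match_ratio
    ))
  }
  matched_controls <- controls |>
    select(-".score") |>
    mutate(matched_to = assignment) |>
    filter(!is.na(.data$matched_to))
  matched_cases <- cases |>
    select(-".score") |>
    mutate(matched_to = NA_character_)
  structure(
    list(
      matched = bind_rows(matched_cases, matched_controls),
      unmatched_cases = unmatched,
      cohort = cohort,
      match_ratio = match_ratio
    ),
    class = "cohort_match"
  )
}

#' @export
print.cohort_match <- function(x, ...) {
  n_case <- sum(x$matched$group == "case")
  n_ctrl <- sum(x$matched$group == "control")
  cat(sprintf(
    "<cohort_match> %d cases, %d matched controls (ratio %d)\n",
    n_case, n_ctrl, x$match_ratio
  ))
  invisible(x)
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences (difference in means over the pooled SD,
#' `sqrt((s1^2 + s2^2)/2)`; categorical covariates are expanded to level
#' indicators) and two-sample tests per covariate, for case vs all controls
#' (before) and case vs matched controls (after). Continuous covariates use
#' Welch's t-test, binary indicators a chi-square test.
#'
#' @param match A [match_controls()] result.
#' @param covariates Covariate columns; defaults as in [fit_propensity()],
#'   plus `age` when present.
#' @return A tibble with `covariate`, `type`, `smd_before`, `smd_after`,
#'   `p_before`, `p_after`.
#' @export
balance_table <- function(match, covariates = NULL) {
  stopifnot(inherits(match, "cohort_match"))
  cohort <- match$cohort
  matched <- match$matched
  if (sum(matched$group == "control") == 0) {
    abort("No matched controls; balance is undefined.")
  }
  covariates <- covariates %||%
    intersect(propensity_covariates(), names(cohort))
  cases <- cohort[cohort$group == "case", ]
  all_ctrl <- cohort[cohort$group == "control", ]
  m_ctrl <- matched[matched$group == "control", ]

  expand <- function(df, cv) {
    x <- df[[cv]]
    if (is.numeric(x)) {
      setNames(list(as.numeric(x)), cv)
    } else if (is.logical(x)) {
      setNames(list(as.numeric(x)), cv)
    } else {
      lv <- sort(unique(cohort[[cv]]))
      setNames(
        lapply(lv, function(l) as.numeric(x == l)),
        paste0(cv, "_", lv)
      )
    }
  }
  rows <- list()
  for (cv in covariates) {
    ex_case <- expand(cases, cv)
    ex_all <- expand(all_ctrl, cv)
    ex_m <- expand(m_ctrl, cv)
    binary <- !is.numeric(cases[[cv]])
    for (nm in names(ex_case)) {
      rows[[length(rows) + 1]] <- tibble(
        covariate = nm,
        type = if (binary) "binary" else "continuous",
        smd_before = smd(ex_case[[nm]], ex_all[[nm]]),
        smd_after = smd(ex_case[[nm]], ex_m[[nm]]),
        p_before = balance_p(ex_case[[nm]], ex_all[[nm]], binary),
        p_after = balance_p(ex_case[[nm]], ex_m[[nm]], binary)
      )
    }
  }
  list_rbind(rows)
}

smd <- function(x, y) {
  s <- sqrt((var(x) + var(y)) / 2)
  if (s == 0) 0 else (mean(x) - mean(y)) / s
}

balance_p <- function(x, y, binary) {
  if (binary) {
    tab <- rbind(c(sum(x), length(x) - sum(x)), c(sum(y), length(y) - sum(y)))
    if (any(colSums(tab) == 0)) return(NA_real_)
    suppressWarnings(chisq.test(tab)$p.value)
  } else {
    if (var(x) == 0 && var(y) == 0) return(NA_real_)
    t.test(x, y)$p.value
  }
}
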