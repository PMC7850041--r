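utils::globalVariables("where")

#' Tidy an SME result
#'
#' One row per channel x frequency with the Welch subsequent-memory
#' t-statistic.
#'
#' @param x An `sme_result`.
#' @param ... Unused.
#' @return A tibble with `channel`, `frequency`, `t`.
#' @method tidy sme_result
#' @export
tidy.sme_result <- function(x, ...) {
  tidyr::expand_grid(
    channel = x$channels,
    frequency = x$freqs
  ) |>
    arrange(match(.data$channel, x$channels)) |>
    mutate(t = as.vector(t(x$t_stats)))
}

#' @rdname tidy.sme_result
#' @method glance sme_result
#' @export
glance.sme_result <- function(x, ...) {
  tibble(
    n_channels = nrow(x$t_stats), n_freqs = ncol(x$t_stats),
    n_recalled = x$n_recalled, n_not_recalled = x$n_not_recalled,
    mean_t = mean(x$t_stats)
  )
}

#' Tidy a theta connectivity network
#'
#' @param x A `theta_network`.
#' @param ... Unused.
#' @return The channel-pair edge tibble (`ch_a`, `ch_b`, `observed_sme`, `z`).
#' @method tidy theta_network
#' @export
tidy.theta_network <- function(x, ...) x$pair_z

#' @rdname tidy.theta_network
#' @method glance theta_network
#' @export
glance.theta_network <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pair_z), n_perm = x$n_perm,
    mean_z = mean(x$pair_z$z, na.rm = TRUE),
    n_significant = sum(abs(x$pair_z$z) > 1.96, na.rm = TRUE)
  )
}

#' Tidy a classifier result
#'
#' @param x A `classifier_result`.
#' @param ... Unused.
#' @return The pooled out-of-fold prediction tibble.
#' @method tidy classifier_result
#' @export
tidy.classifier_result <- function(x, ...) x$predictions

#' @rdname tidy.classifier_result
#' @method glance classifier_result
#' @export
glance.classifier_result <- function(x, ...) {
  tibble(
    auc = x$auc, fold_scheme = x$fold_scheme, n_folds = x$n_folds,
    C = x$C, n_items = nrow(x$predictions)
  )
}

#' Tidy a penalized logistic fit
#'
#' @param x A `logreg_fit`.
#' @param ... Unused.
#' @return A tibble with `term` (`"(Intercept)"` and feature indices) and
#'   `estimate`.
#' @method tidy logreg_fit
#' @export
tidy.logreg_fit <- function(x, ...) {
  tibble(
    term = c("(Intercept)", paste0("x", seq_along(x$weights))),
    estimate = c(x$intercept, x$weights)
  )
}

#' Tidy a cohort match
#'
#' @param x A `cohort_match`.
#' @param ... Unused.
#' @return The matched cohort tibble (cases plus matched controls with
#'   `matched_to`).
#' @method tidy cohort_match
#' @export
tidy.cohort_match <- function(x, ...) as_tibble(x$matched)

#' @rdname tidy.cohort_match
#' @method glance cohort_match
#' @export
glance.cohort_match <- function(x, ...) {
  tibble(
    n_cases = sum(x$matched$group == "case"),
    n_matched_controls = sum(x$matched$group == "control"),
    match_ratio = x$match_ratio,
    n_unmatched_cases = nrow(x$unmatched_cases)
  )
}
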