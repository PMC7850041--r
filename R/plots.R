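#' Plot serial-position curves
#'
#' Per-subject curves as light lines with the group mean +/- SE overlaid
#' when a `groups` table is supplied.
#'
#' @param spc A [serial_position_curve()] result.
#' @param groups Optional tibble with `subject`, `group`.
#' @return A ggplot object.
#' @export
plot_serial_positions <- function(spc, groups = NULL) {
  p <- ggplot(spc, aes(.data$serial_position, .data$p_recall)) +
    labs(
      x = "Serial position", y = "P(recall)",
      title = "Serial-position curve"
    ) +
    scale_x_continuous(breaks = seq(1, 12, 2)) +
    theme_minimal()
  if (is.null(groups)) {
    p + geom_line(aes(group = .data$subject), alpha = 0.4)
  } else {
    gs <- spc |>
      inner_join(groups, by = "subject") |>
      summarise(
        mean_p = mean(.data$p_recall),
        se_p = sd(.data$p_recall) / sqrt(n()),
        .by = c("group", "serial_position")
      )
    p +
      geom_line(aes(group = .data$subject), alpha = 0.15) +
      geom_ribbon(
        data = gs,
        aes(
          y = .data$mean_p,
          ymin = .data$mean_p - .data$se_p,
          ymax = .data$mean_p + .data$se_p,
          fill = .data$group
        ),
        alpha = 0.3
      ) +
      geom_line(
        data = gs,
        aes(y = .data$mean_p, colour = .data$group),
        linewidth = 1
      )
  }
}

#' Heatmap of subsequent-memory t-statistics
#'
#' Channel-by-frequency tile map of the Welch SME t-statistics; blue cells
#' mark power decreases during successful encoding, red cells increases.
#'
#' @param object An `sme_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sme_result
#' @export
autoplot.sme_result <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(factor(round(.data$frequency, 1)), .data$channel, fill = .data$t)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(
      x = "Frequency (Hz)", y = "Channel", fill = "SME t",
      title = "Spectral power subsequent-memory effect"
    ) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
}

#' ROI edge map of a theta connectivity network
#'
#' @param object A `theta_network`.
#' @param electrodes Electrode tibble mapping channels to regions.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot theta_network
#' @export
autoplot.theta_network <- function(object, electrodes, ...) {
  roi_edges(object, electrodes) |>
    ggplot(aes(.data$roi_a, .data$roi_b, fill = .data$mean_z)) +
    geom_tile() +
    geom_text(aes(label = round(.data$mean_z, 2))) +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    labs(
      x = NULL, y = NULL, fill = "Mean Z",
      title = "Theta connectivity SME (permutation Z) by ROI pair"
    ) +
    theme_minimal()
}

#' ROC curve of a cross-validated recall classifier
#'
#' @param object A `classifier_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot classifier_result
#' @export
autoplot.classifier_result <- function(object, ...) {
  ggplot(object$roc, aes(.data$fpr, .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_path(linewidth = 0.8, colour = "#2166ac") +
    coord_equal() +
    labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s ROC (AUC = %.3f)", object$fold_scheme, object$auc)
    ) +
    theme_minimal()
}

#' Covariate balance (love) plot for a matched cohort
#'
#' Absolute standardized mean differences per covariate before (case vs all
#' controls) and after (case vs matched controls) matching.
#'
#' @param object A `cohort_match`.
#' @param ... Passed to [balance_table()].
#' @return A ggplot object.
#' @method autoplot cohort_match
#' @export
autoplot.cohort_match <- function(object, ...) {
  balance_table(object, ...) |>
    tidyr::pivot_longer(
      c("smd_before", "smd_after"),
      names_to = "stage", values_to = "smd"
    ) |>
    mutate(stage = ifelse(.data$stage == "smd_before", "before", "after")) |>
    ggplot(aes(abs(.data$smd), .data$covariate, colour = .data$stage)) +
    geom_vline(xintercept = 0.1, linetype = "dashed", colour = "grey60") +
    geom_point(size = 2) +
    labs(
      x = "|standardized mean difference|", y = NULL, colour = NULL,
      title = "Covariate balance before vs after matching"
    ) +
    theme_minimal()
}
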