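#' Simulation design configuration
#'
#' Describes the study design emulated by the synthetic generator: a delayed
#' free-recall experiment of up to 26 lists (25 after excluding the practice
#' list) of 12 items each, recorded on a multichannel intracranial montage.
#' In the categorized task variant each list carries exactly 3 taxonomic
#' categories x 4 exemplars, presented as successive same-category pairs with
#' successive pairs drawn from distinct categories.
#'
#' @param n_sessions Sessions per subject.
#' @param n_lists Scored (non-practice) lists per session. Default 25.
#' @param items_per_list Items per list; fixed at 12 by the task design.
#' @param task_variant `"unrelated"` or `"categorized"`.
#' @param fs Sampling rate in samples/s. Default 500, which keeps the Nyquist
#'   frequency above the highest analysis frequency (180 Hz).
#' @param n_channels Number of recording channels.
#' @param region_labels Region-of-interest labels cycled over channels.
#' @param epoch_window Analysis span of each epoch in seconds relative to
#'   item onset, `c(start, end)`, excluding the buffer. Must cover the
#'   encoding windows used downstream (0.4--1.1 s and 0--1.366 s).
#' @param buffer Edge buffer in seconds synthesised on each side of the
#'   epoch for wavelet edge control. Default 1 s, at least three wavelet
#'   standard deviations at the lowest analysis frequency (3 Hz).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sessions = 1,
                       n_lists = 25,
                       items_per_list = 12,
                       task_variant = c("unrelated", "categorized"),
                       fs = 500,
                       n_channels = 8,
                       region_labels = c("frontal", "MTL", "LTC", "parietal"),
                       epoch_window = c(0, 1.4),
                       buffer = 1.0) {
  task_variant <- match.arg(task_variant)
  if (items_per_list != 12) {
    abort("items_per_list is fixed at 12 by the task design.")
  }
  if (fs < 2 * 180) {
    abort("fs must be at least twice the highest analysis frequency (180 Hz).")
  }
  stopifnot(
    n_sessions >= 1, n_lists >= 1, n_channels >= 1,
    length(epoch_window) == 2, epoch_window[2] > epoch_window[1], buffer >= 0
  )
  structure(
    list(
      n_sessions = as.integer(n_sessions),
      n_lists = as.integer(n_lists),
      items_per_list = 12L,
      task_variant = task_variant,
      fs = fs,
      n_channels = as.integer(n_channels),
      region_labels = region_labels,
      epoch_window = as.numeric(epoch_window),
      buffer = as.numeric(buffer)
    ),
    class = "sim_config"
  )
}

#' Ground-truth effect sizes for the synthetic generator
#'
#' Encodes, as generator parameters, the memory effects under study: a
#' serial-position-shaped recall probability with primacy and recency,
#' temporal and semantic clustering of recall order, a theta (4--8 Hz) power
#' decrease and a high-frequency (45--170 Hz) power increase on later-recalled
#' items, and increased theta phase coupling between designated channel pairs
#' during successful encoding.
#'
#' @param recall_base Recall probability per serial position (length 12).
#'   The default has mild primacy and recency around a ~35% base rate,
#'   typical of delayed free recall.
#' @param temporal_clustering_strength Non-negative temporal kernel decay of
#'   the recall-order sampler; 0 gives order uniform among recalled items.
#' @param semantic_clustering_strength Non-negative log-odds bonus for
#'   same-category transitions in the recall-order sampler.
#' @param theta_power_delta Signed log-power shift (approximately z-units)
#'   applied in the theta band (4--8 Hz) to recalled items. Negative by
#'   default: successful encoding shows a theta power decrease.
#' @param hfa_power_delta Signed log-power shift applied in the
#'   high-frequency band (45--170 Hz) to recalled items. Positive by default.
#' @param sync_pairs List of length-2 character vectors naming channel pairs
#'   that share a theta phase component.
#' @param sync_plv_delta Increase in the shared fraction of theta-band power
#'   on recalled items for `sync_pairs`; the empirical phase-locking-value
#'   difference is approximately this value. Must keep the shared fraction
#'   in \[0, 1\].
#' @param sync_base Baseline shared theta fraction on not-recalled items.
#' @param noise_exponent Spectral exponent of the 1/f background (power
#'   ~ f^-exponent).
#' @return A list of class `effect_truth`.
#' @export
effect_truth <- function(recall_base = default_recall_base(),
                         temporal_clustering_strength = 0.7,
                         semantic_clustering_strength = 0.5,
                         theta_power_delta = -0.5,
                         hfa_power_delta = 1.0,
                         sync_pairs = list(),
                         sync_plv_delta = 0.3,
                         sync_base = 0.1,
                         noise_exponent = 1.0) {
  if (any(recall_base < 0 | recall_base > 1) || length(recall_base) != 12) {
    abort("recall_base must be 12 probabilities in [0, 1].")
  }
  stopifnot(
    temporal_clustering_strength >= 0, semantic_clustering_strength >= 0,
    is.finite(theta_power_delta), is.finite(hfa_power_delta),
    sync_base >= 0, sync_base + sync_plv_delta <= 1,
    sync_base + sync_plv_delta >= 0, noise_exponent >= 0
  )
  structure(
    list(
      recall_base = recall_base,
      temporal_clustering_strength = temporal_clustering_strength,
      semantic_clustering_strength = semantic_clustering_strength,
      theta_power_delta = theta_power_delta,
      hfa_power_delta = hfa_power_delta,
      sync_pairs = sync_pairs,
      sync_plv_delta = sync_plv_delta,
      sync_base = sync_base,
      noise_exponent = noise_exponent
    ),
    class = "effect_truth"
  )
}

#' Default serial-position recall probabilities
#'
#' Primacy- and recency-shaped recall probabilities for a 12-item list,
#' around a base rate of about 0.35.
#'
#' @return Numeric vector of length 12.
#' @export
default_recall_base <- function() {
  pos <- 1:12
  p <- 0.30 + 0.28 * exp(-(pos - 1) / 1.6) + 0.22 * exp(-(12 - pos) / 1.3)
  pmin(p, 1)
}

#' Null effect truth
#'
#' Convenience constructor with every injected effect set to zero: recall
#' probability flat at `p`, recall order uniform among recalled items, and no
#' power or synchrony difference between recalled and not-recalled epochs.
#' Downstream statistics computed on data generated under this truth follow
#' their null distributions.
#'
#' @param p Flat recall probability.
#' @return An [effect_truth()].
#' @export
null_truth <- function(p = 0.5) {
  effect_truth(
    recall_base = rep(p, 12),
    temporal_clustering_strength = 0,
    semantic_clustering_strength = 0,
    theta_power_delta = 0,
    hfa_power_delta = 0,
    sync_pairs = list(),
    sync_plv_delta = 0,
    sync_base = 0
  )
}

#' Default electrode table for a simulated montage
#'
#' Assigns region labels to `n_channels` channels by cycling over
#' `region_labels`, with no excluded channels.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `channel`, `region`, `excluded`.
#' @export
simulate_electrodes <- function(config) {
  tibble(
    channel = paste0("ch", seq_len(config$n_channels)),
    region = rep_len(config$region_labels, config$n_channels),
    excluded = FALSE
  )
}
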