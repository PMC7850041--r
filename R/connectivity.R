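#' Per-item theta phase differences for a channel pair
#'
#' Extracts instantaneous phase from the complex Morlet decomposition at the
#' theta frequencies and returns, for every item and frequency, the circular
#' mean of the phase-difference time series over the encoding window.
#'
#' @param epochs An [epoch_tensor()].
#' @param pair Length-2 character (or integer) vector naming the channel
#'   pair.
#' @param freqs Theta frequencies in Hz; default 4, 5, 6, 7, 8.
#' @param window Analysis window in seconds relative to item onset.
#' @param wave_number Wavelet cycles parameter.
#' @return A numeric matrix items x frequencies of circular-mean phase
#'   differences in (-pi, pi].
#' @export
item_phase_difference <- function(epochs, pair, freqs = 4:8,
                                  window = c(0.4, 1.1), wave_number = 5) {
  stopifnot(length(pair) == 2)
  sub <- subset(epochs, channels = pair)
  dec <- morlet_decompose(sub, freqs, wave_number = wave_number, window = window)
  u <- dec$coef / Mod(dec$coef)
  d <- u[, 1, , , drop = FALSE] * Conj(u[, 2, , , drop = FALSE])
  Arg(rowMeans(d, dims = 3)[, 1, ]) # items x freqs
}

# Unit phasors of the per-item circular-mean phase difference for every
# usable channel pair: complex matrix items x (pairs * freqs), plus the pair
# index table. Shared by the observed and permuted PLV computations.
pairwise_phase_phasors <- function(epochs, electrodes, freqs, window, wave_number) {
  dec <- morlet_decompose(epochs, freqs, wave_number = wave_number, window = window)
  u <- dec$coef / Mod(dec$coef)
  n_ch <- dim(u)[2]
  if (n_ch < 2) abort("At least two usable channels are required.")
  pairs <- utils::combn(n_ch, 2)
  n_items <- dim(u)[1]
  n_f <- length(freqs)
  p_mat <- matrix(0i, n_items, ncol(pairs) * n_f)
  for (j in seq_len(ncol(pairs))) {
    dphi <- u[, pairs[1, j], , , drop = FALSE] * Conj(u[, pairs[2, j], , , drop = FALSE])
    m <- rowMeans(dphi, dims = 3)[, 1, ] # items x freqs, complex
    mm <- Mod(m)
    m <- ifelse(mm == 0, 0i, m / mm) # unit phasor of the mean direction
    p_mat[, ((j - 1) * n_f + 1):(j * n_f)] <- m
  }
  list(
    phasors = p_mat,
    pairs = tibble(
      ch_a = epochs$channels[pairs[1, ]],
      ch_b = epochs$channels[pairs[2, ]]
    ),
    n_freqs = n_f
  )
}

#' Phase-locking value by item class
#'
#' PLV = magnitude of the mean unit phasor of phase differences across items,
#' computed separately for recalled and not-recalled items at each frequency.
#'
#' @param phase_diffs Matrix items x frequencies of phase differences in
#'   radians (e.g. from [item_phase_difference()]).
#' @param recalled Logical vector, one flag per item.
#' @return A tibble with `class`, `frequency` (column index), `plv`, `n_items`.
#' @export
plv_by_class <- function(phase_diffs, recalled) {
  phase_diffs <- as.matrix(phase_diffs)
  recalled <- as.logical(recalled)
  stopifnot(nrow(phase_diffs) == length(recalled))
  if (sum(recalled) < 2 || sum(!recalled) < 2) {
    abort("plv_by_class() needs at least two items per class.")
  }
  z <- exp(1i * phase_diffs)
  one <- function(cls, idx) {
    tibble(
      class = cls,
      frequency = seq_len(ncol(phase_diffs)),
      plv = Mod(colMeans(z[idx, , drop = FALSE])),
      n_items = length(idx)
    )
  }
  bind_rows(one("recalled", which(recalled)), one("not_recalled", which(!recalled)))
}

#' Permutation-calibrated theta connectivity SME network
#'
#' For every usable channel pair, the connectivity subsequent-memory effect
#' is the recalled-minus-not-recalled difference in phase-locking value,
#' averaged over the five theta frequencies. Its null distribution is built
#' by shuffling the recalled/not-recalled item labels (`n_perm` times, the
#' same shuffle sequence applied to every pair, preserving class sizes and
#' cross-pair dependence), and each pair's observed SME is standardised
#' against its own null: Z = (observed - null mean) / null SD. Positive Z
#' means greater theta synchronization during successful encoding.
#'
#' @param epochs An [epoch_tensor()].
#' @param electrodes Electrode tibble; excluded channels are dropped.
#' @param recalled Logical vector, one flag per item.
#' @param freqs Theta frequencies; default 4--8 Hz in 1 Hz steps.
#' @param window Analysis window in seconds.
#' @param n_perm Number of label shuffles (default 500).
#' @param rng_seed Integer seed for the shuffle sequence.
#' @param wave_number Wavelet cycles parameter.
#' @return An object of class `theta_network`: list with `pair_z` (tibble
#'   `ch_a`, `ch_b`, `observed_sme`, `z`), `n_perm`, `freqs`, `window`.
#' @export
connectivity_sme_z <- function(epochs, electrodes, recalled,
                               freqs = 4:8, window = c(0.4, 1.1),
                               n_perm = 500, rng_seed = 1,
                               wave_number = 5) {
  assert_electrodes(electrodes)
  recalled <- as.logical(recalled)
  stopifnot(dim(epochs$data)[1] == length(recalled))
  if (sum(recalled) < 2 || sum(!recalled) < 2) {
    abort("connectivity_sme_z() needs at least two items per class.")
  }
  keep <- electrodes$channel[!electrodes$excluded]
  epochs <- subset(epochs, channels = keep)
  pp <- pairwise_phase_phasors(epochs, electrodes, freqs, window, wave_number)

  set.seed(as.integer(rng_seed))
  n_items <- length(recalled)
  n_rec <- sum(recalled)
  # indicator matrix of recalled labels: observed + n_perm shuffles
  ind <- matrix(0, n_items, n_perm + 1L)
  ind[which(recalled), 1L] <- 1
  for (b in seq_len(n_perm)) {
    ind[sample.int(n_items, n_rec), b + 1L] <- 1
  }
  tot <- colSums(pp$phasors) # complex, per pair x freq column
  s_rec <- t(pp$phasors) %*% ind # (pairs*freqs) x (n_perm+1), complex sums
  plv_rec <- Mod(s_rec) / n_rec
  plv_not <- Mod(tot - s_rec) / (n_items - n_rec)
  sme <- plv_rec - plv_not
  # average over frequencies: rows are pair-major blocks of n_freqs
  n_pairs <- nrow(pp$pairs)
  grp <- rep(seq_len(n_pairs), each = pp$n_freqs)
  sme_pair <- rowsum(sme, grp) / pp$n_freqs # pairs x (n_perm+1)
  obs <- sme_pair[, 1L]
  nulls <- sme_pair[, -1L, drop = FALSE]
  mu <- rowMeans(nulls)
  sdv <- sqrt(rowSums((nulls - mu)^2) / (n_perm - 1))
  z <- (obs - mu) / sdv
  if (any(sdv == 0)) {
    warn("Null SD was zero for some pair(s); their Z is set to NA.")
    z[sdv == 0] <- NA_real_
  }
  structure(
    list(
      pair_z = tibble(
        ch_a = pp$pairs$ch_a, ch_b = pp$pairs$ch_b,
        observed_sme = obs, z = z
      ),
      n_perm = n_perm, freqs = freqs, window = window,
      n_recalled = n_rec, n_items = n_items
    ),
    class = "theta_network"
  )
}

#' @export
print.theta_network <- function(x, ...) {
  cat(sprintf(
    "<theta_network> %d channel pairs, %d permutations; mean Z = %.3f\n",
    nrow(x$pair_z), x$n_perm, mean(x$pair_z$z, na.rm = TRUE)
  ))
  invisible(x)
}

#' Aggregate a theta network to region-of-interest pair edges
#'
#' ROI-pair edge weight = mean permutation Z over all channel pairs spanning
#' that (unordered) region pair; within-region pairs form the diagonal
#' edges.
#'
#' @param network A [connectivity_sme_z()] result.
#' @param electrodes Electrode tibble mapping channels to regions.
#' @return A tibble with `roi_a`, `roi_b`, `mean_z`, `n_pairs`.
#' @export
roi_edges <- function(network, electrodes) {
  stopifnot(inherits(network, "theta_network"))
  assert_electrodes(electrodes)
  reg <- setNames(electrodes$region, electrodes$channel)
  pz <- network$pair_z |>
    filter(!is.na(.data$z)) |>
    mutate(
      roi_a = pmin(reg[.data$ch_a], reg[.data$ch_b]),
      roi_b = pmax(reg[.data$ch_a], reg[.data$ch_b])
    )
  pz |>
    summarise(
      mean_z = mean(.data$z), n_pairs = n(),
      .by = c("roi_a", "roi_b")
    ) |>
    arrange(.data$roi_a, .data$roi_b)
}

#' Edges above the display threshold
#'
#' Channel-pair edges whose |Z| exceeds a threshold (1.96 by default), the
#' convention used when rendering connectivity networks.
#'
#' @param network A [connectivity_sme_z()] result.
#' @param threshold Absolute-Z display threshold.
#' @return The `pair_z` tibble restricted to supra-threshold edges.
#' @export
significant_edges <- function(network, threshold = 1.96) {
  filter(network$pair_z, abs(.data$z) > threshold)
}

#' Group statistics on ROI network edge weights
#'
#' Each subject is summarised by the mean edge weight over their ROI-pair
#' edges; each group's weights are compared to zero with a one-sample t-test
#' (positive mean = net synchronization increase during successful
#' encoding), and the two groups are compared with a Welch two-sample
#' t-test.
#'
#' @param edge_tbl Tibble of per-subject ROI edges: `subject`, `roi_a`,
#'   `roi_b`, `mean_z` (e.g. [roi_edges()] row-bound over subjects).
#' @param groups Tibble with `subject`, `group`.
#' @return A list with `subject_means` (tibble `subject`, `group`,
#'   `mean_edge`), `one_sample` (per-group t, df, p), `two_sample` (one-row
#'   tibble).
#' @export
network_group_stats <- function(edge_tbl, groups) {
  subj <- edge_tbl |>
    summarise(mean_edge = mean(.data$mean_z), n_edges = n(), .by = "subject") |>
    inner_join(groups, by = "subject")
  dropped <- setdiff(groups$subject, subj$subject)
  if (length(dropped) > 0) {
    inform(paste0(
      "Subjects without ROI edges excluded from group tests: ",
      paste(dropped, collapse = ", ")
    ))
  }
  one_sample <- subj |>
    group_by(.data$group) |>
    group_modify(function(df, key) {
      ht <- t.test(df$mean_edge, mu = 0)
      tibble(
        mean_edge = mean(df$mean_edge), t = unname(ht$statistic),
        df = unname(ht$parameter), p_value = ht$p.value, n_subjects = nrow(df)
      )
    }) |>
    ungroup()
  gl <- sort(unique(subj$group))
  two_sample <- if (length(gl) == 2) {
    ht <- t.test(
      subj$mean_edge[subj$group == gl[1]],
      subj$mean_edge[subj$group == gl[2]]
    )
    tibble(
      t = unname(ht$statistic), df = unname(ht$parameter), p_value = ht$p.value,
      group_1 = gl[1], group_2 = gl[2]
    )
  } else {
    NULL
  }
  list(subject_means = subj, one_sample = one_sample, two_sample = two_sample)
}
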