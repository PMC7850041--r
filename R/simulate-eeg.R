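#' Simulate epoched multichannel iEEG with injectable memory effects
#'
#' Synthesises one voltage epoch per event row on every channel. Each epoch
#' is 1/f-shaped Gaussian noise built by spectral shaping of white noise;
#' recalled items receive a theta-band (4--8 Hz) log-power shift
#' (`theta_power_delta`, negative by default) and a broadband high-frequency
#' (45--170 Hz) log-power shift (`hfa_power_delta`), applied on the synthesis
#' spectrum. For each channel pair in `truth$sync_pairs`, a shared narrowband
#' theta component replaces a fraction of both channels' intrinsic theta
#' power; the shared fraction is `sync_base` on not-recalled items and
#' `sync_base + sync_plv_delta` on recalled items, so phase locking between
#' the pair increases during successful encoding by approximately
#' `sync_plv_delta`.
#'
#' Epochs span the configured analysis window plus a buffer on each side;
#' buffer samples are genuine signal (the noise process is stationary) and
#' are trimmed after wavelet convolution downstream.
#'
#' @param events Events tibble, e.g. from [simulate_behavior()]; one epoch is
#'   generated per row.
#' @param electrodes Electrode tibble, e.g. from [simulate_electrodes()].
#' @param config A [sim_config()].
#' @param truth An [effect_truth()].
#' @param rng_seed Integer seed; identical seeds give identical tensors.
#' @return An [epoch_tensor()] whose item axis aligns 1:1 with `events` rows.
#' @export
simulate_eeg_epochs <- function(events, electrodes, config, truth, rng_seed) {
  assert_events(events)
  assert_electrodes(electrodes)
  stopifnot(inherits(config, "sim_config"), inherits(truth, "effect_truth"))
  if (config$epoch_window[1] > 0.4 || config$epoch_window[2] < 1.1) {
    abort("epoch_window must cover the 0.4--1.1 s encoding window.")
  }
  set.seed(as.integer(rng_seed))

  fs <- config$fs
  n <- round((diff(config$epoch_window) + 2 * config$buffer) * fs)
  n_items <- nrow(events)
  channels <- electrodes$channel
  n_ch <- length(channels)
  recalled <- events$recalled

  freq <- abs(fft_freqs(n, fs))
  env0 <- base_amplitude(freq, truth$noise_exponent)
  env0 <- env0 * 50 / sqrt(mean(env0^2)) # cosmetic microvolt-ish scale
  theta_idx <- which(freq >= 4 & freq <= 8)
  hfa_idx <- which(freq >= 45 & freq <= 170)

  sync_ch <- unlist(truth$sync_pairs)
  if (anyDuplicated(sync_ch)) {
    abort("A channel may appear in at most one sync pair.")
  }
  if (!all(sync_ch %in% channels)) {
    abort("sync_pairs name channels absent from the electrode table.")
  }
  # shared theta fraction per item
  rho <- ifelse(recalled, truth$sync_base + truth$sync_plv_delta, truth$sync_base)

  # shared narrowband theta spectra, one per sync pair (freq x item, theta rows)
  shared <- map(truth$sync_pairs, function(p) {
    mvfft(matrix(rnorm(n * n_items), n, n_items))[theta_idx, , drop = FALSE]
  })
  pair_of <- rep(NA_integer_, n_ch)
  for (i in seq_along(truth$sync_pairs)) {
    pair_of[match(truth$sync_pairs[[i]], channels)] <- i
  }

  out <- array(0, dim = c(n_items, n_ch, n))
  th_mult <- ifelse(recalled, exp(truth$theta_power_delta / 2), 1)
  hf_mult <- ifelse(recalled, exp(truth$hfa_power_delta / 2), 1)
  for (c_i in seq_len(n_ch)) {
    f_mat <- mvfft(matrix(rnorm(n * n_items), n, n_items)) * env0
    # band-limited log-power shifts on recalled items
    f_mat[theta_idx, ] <- f_mat[theta_idx, ] * rep(th_mult, each = length(theta_idx))
    f_mat[hfa_idx, ] <- f_mat[hfa_idx, ] * rep(hf_mult, each = length(hfa_idx))
    p_i <- pair_of[c_i]
    if (!is.na(p_i)) {
      # replace a fraction rho of theta power by the pair-shared component
      f_mat[theta_idx, ] <- f_mat[theta_idx, ] * rep(sqrt(1 - rho), each = length(theta_idx)) +
        shared[[p_i]] * (env0[theta_idx] %o% (sqrt(rho) * th_mult))
    }
    x <- Re(mvfft(f_mat, inverse = TRUE)) / n
    out[, c_i, ] <- t(x)
  }
  epoch_tensor(
    out,
    fs = fs, t_start = config$epoch_window[1] - config$buffer,
    buffer = config$buffer, channels = channels
  )
}

# Amplitude envelope for 1/f^exponent power: amplitude ~ f^(-exponent/2),
# flattened below 1 Hz, zero at DC.
base_amplitude <- function(freq, exponent) {
  env <- pmax(freq, 1)^(-exponent / 2)
  env[freq == 0] <- 0
  env
}

#' Simulate a full single-subject dataset
#'
#' Behaviour, electrode table and epoched signals for one subject under one
#' ground truth, with all randomness derived from one seed.
#'
#' @inheritParams simulate_behavior
#' @return A list with elements `events`, `electrodes`, `epochs`, `truth`,
#'   `config`, of class `subject_dataset`.
#' @export
simulate_subject <- function(config, truth, rng_seed, subject = "s01") {
  events <- simulate_behavior(
    config, truth, derive_seed(rng_seed, "behavior"), subject = subject
  )
  electrodes <- simulate_electrodes(config)
  epochs <- simulate_eeg_epochs(
    events, electrodes, config, truth, derive_seed(rng_seed, "eeg")
  )
  structure(
    list(
      events = events, electrodes = electrodes, epochs = epochs,
      truth = truth, config = config
    ),
    class = "subject_dataset"
  )
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf(
    "<subject_dataset> %s: %d events (%0.1f%% recalled), %d channels\n",
    x$events$subject[1], nrow(x$events), 100 * mean(x$events$recalled),
    length(x$electrodes$channel)
  ))
  invisible(x)
}
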