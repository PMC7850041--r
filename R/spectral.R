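#' Preprocess epoched iEEG
#'
#' Drops channels flagged as excluded (epileptogenic or inter-ictally
#' spiking), optionally re-references a monopolar montage to bipolar
#' neighbour differences, and removes 60 Hz line noise with a fourth-order
#' Butterworth band-stop (58--62 Hz) applied forward-backward so the filter
#' is zero-phase.
#'
#' @param epochs An [epoch_tensor()].
#' @param electrodes Electrode tibble with `channel`, `region`, `excluded`.
#' @param reference `"none"` when the input is already bipolar (the
#'   referencing step is then the identity) or `"bipolar"` to difference
#'   neighbouring channels; the derived channel `a-b` inherits the region of
#'   `a`.
#' @param notch Logical; apply the 60 Hz notch.
#' @return A list with the filtered `epochs` and the `electrodes` table
#'   restricted (and possibly re-derived) to the analysed channels.
#' @export
preprocess_epochs <- function(epochs, electrodes,
                              reference = c("none", "bipolar"),
                              notch = TRUE) {
  reference <- match.arg(reference)
  assert_electrodes(electrodes)
  stopifnot(inherits(epochs, "epoch_tensor"))
  keep <- electrodes$channel[!electrodes$excluded]
  if (length(keep) == 0) abort("All channels are excluded.")
  epochs <- subset(epochs, channels = keep)
  electrodes <- electrodes[match(keep, electrodes$channel), ]

  if (reference == "bipolar") {
    if (length(keep) < 2) abort("Bipolar referencing needs at least 2 channels.")
    a <- seq_len(length(keep) - 1L)
    data <- epochs$data[, a, , drop = FALSE] - epochs$data[, a + 1L, , drop = FALSE]
    labels <- paste0(keep[a], "-", keep[a + 1L])
    epochs <- epoch_tensor(
      data,
      fs = epochs$fs, t_start = epochs$t_start,
      buffer = epochs$buffer, channels = labels
    )
    electrodes <- tibble(
      channel = labels, region = electrodes$region[a], excluded = FALSE
    )
  }

  if (notch) {
    if (epochs$fs <= 124) abort("Sampling rate too low for a 60 Hz notch.")
    bf <- signal::butter(4, c(58, 62) / (epochs$fs / 2), type = "stop")
    d <- dim(epochs$data)
    flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
    for (j in seq_len(ncol(flat))) {
      flat[, j] <- signal::filtfilt(bf, flat[, j])
    }
    epochs$data <- aperm(array(flat, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
    dimnames(epochs$data) <- list(NULL, epochs$channels, NULL)
  }
  list(epochs = epochs, electrodes = electrodes)
}

#' Morlet wavelet decomposition
#'
#' Convolves every epoch with complex Morlet wavelets (default wave number
#' 5: the Gaussian envelope holds about five cycles at each centre
#' frequency) and returns the complex coefficients restricted to an analysis
#' window. Convolution is done in the frequency domain; the epoch buffer
#' absorbs wrap-around, and buffer samples are excluded by the window.
#'
#' @param epochs An [epoch_tensor()] whose buffer is at least three wavelet
#'   standard deviations at the lowest frequency.
#' @param freqs Centre frequencies in Hz, all below Nyquist.
#' @param wave_number Wavelet cycles parameter (envelope SD in time is
#'   `wave_number / (2 pi f)`).
#' @param window Analysis window `c(start, end)` in seconds relative to item
#'   onset; defaults to the full unbuffered epoch.
#' @return A list with the complex array `coef` (items x channels x
#'   frequencies x samples), `freqs`, and sample `times`.
#' @export
morlet_decompose <- function(epochs, freqs, wave_number = 5, window = NULL) {
  stopifnot(inherits(epochs, "epoch_tensor"), wave_number > 0)
  if (any(freqs >= epochs$fs / 2)) {
    abort("All wavelet frequencies must be below Nyquist.")
  }
  if (any(freqs <= 0)) abort("Wavelet frequencies must be positive.")
  sigma_t <- wave_number / (2 * pi * min(freqs))
  if (epochs$buffer < 3 * sigma_t) {
    warn(sprintf(
      "Epoch buffer (%.2f s) is below 3 wavelet SDs (%.2f s) at %.2f Hz; edge effects may leak into the analysis window.",
      epochs$buffer, 3 * sigma_t, min(freqs)
    ))
  }
  d <- dim(epochs$data)
  n <- d[3]
  win_idx <- if (is.null(window)) {
    window_index(epochs, c(epochs$t_start + epochs$buffer,
                           epoch_times(epochs)[n] - epochs$buffer))
  } else {
    window_index(epochs, window)
  }
  fgrid <- fft_freqs(n, epochs$fs)
  # signals in columns: samples x (items * channels)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)
  f_sig <- mvfft(flat)
  out <- array(
    0i,
    dim = c(d[1], d[2], length(freqs), length(win_idx)),
    dimnames = list(NULL, epochs$channels, NULL, NULL)
  )
  for (k in seq_along(freqs)) {
    h <- morlet_kernel_fft(fgrid, freqs[k], wave_number)
    w <- mvfft(f_sig * h, inverse = TRUE)[win_idx, , drop = FALSE] / n
    out[, , k, ] <- aperm(array(w, dim = c(length(win_idx), d[1], d[2])), c(2, 3, 1))
  }
  list(coef = out, freqs = freqs, times = epoch_times(epochs)[win_idx])
}

# Frequency response of the analytic Morlet wavelet: a Gaussian of SD
# f0/wave_number centred on f0, zero on negative frequencies. Peak response 1
# so a unit sinusoid at f0 yields |coef| ~ 1/2 (its positive-frequency half).
morlet_kernel_fft <- function(fgrid, f0, wave_number) {
  sigma_f <- f0 / wave_number
  h <- exp(-0.5 * ((fgrid - f0) / sigma_f)^2)
  h[fgrid < 0] <- 0
  h
}

#' Morlet power time series
#'
#' Squared magnitude of [morlet_decompose()].
#'
#' @inheritParams morlet_decompose
#' @return A list with `power` (items x channels x frequencies x samples),
#'   `freqs`, `times`.
#' @export
morlet_power <- function(epochs, freqs, wave_number = 5, window = NULL) {
  dec <- morlet_decompose(epochs, freqs, wave_number = wave_number, window = window)
  list(power = Mod(dec$coef)^2, freqs = dec$freqs, times = dec$times)
}

#' Encoding spectral power features
#'
#' The per-item power features of the subsequent-memory analysis: Morlet log
#' power averaged over an encoding window, z-scored over items within each
#' session separately for every channel x frequency. The default grid is 20
#' wavelets log-spaced on 3--170 Hz and the window is 0.4--1.1 s after item
#' onset.
#'
#' @param epochs An [epoch_tensor()] aligned 1:1 with `events` rows.
#' @param events Events tibble providing the session of each item.
#' @param freqs Frequency grid in Hz.
#' @param window Averaging window in seconds relative to item onset.
#' @param wave_number Wavelet cycles parameter.
#' @param z_score Z-score within session (the default); disabling returns
#'   window-averaged log power.
#' @return An object of class `power_features`: list with `values` (items x
#'   channels x frequencies), `freqs`, `window`, `session`, `channels`.
#' @export
encoding_power_features <- function(epochs, events,
                                    freqs = log_spaced_freqs(3, 170, 20),
                                    window = c(0.4, 1.1),
                                    wave_number = 5,
                                    z_score = TRUE) {
  assert_events(events)
  stopifnot(dim(epochs$data)[1] == nrow(events))
  dec <- morlet_decompose(epochs, freqs, wave_number = wave_number, window = window)
  # mean log power over the window
  lp <- log(Mod(dec$coef)^2)
  vals <- rowMeans(lp, dims = 3)
  session <- events$session
  if (z_score) {
    for (ses in unique(session)) {
      idx <- which(session == ses)
      if (length(idx) < 2) {
        abort(sprintf("Session '%s' has a single item; z-scoring is undefined.", ses))
      }
      sub <- vals[idx, , , drop = FALSE]
      mu <- colMeans(sub)
      sdv <- sqrt(colMeans(sweep(sub, c(2, 3), mu)^2) * length(idx) / (length(idx) - 1))
      if (any(sdv == 0)) {
        warn("Constant power across items in some channel x frequency cell; feature set to 0.")
      }
      z <- sweep(sweep(sub, c(2, 3), mu), c(2, 3), ifelse(sdv == 0, 1, sdv), "/")
      z[rep(sdv == 0, each = length(idx))] <- 0
      vals[idx, , ] <- z
    }
  }
  structure(
    list(
      values = vals, freqs = freqs, window = window,
      session = session, channels = epochs$channels
    ),
    class = "power_features"
  )
}

#' @export
print.power_features <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<power_features> %d items x %d channels x %d freqs (%.3g-%.3g Hz), window %g-%g s\n",
    d[1], d[2], d[3], min(x$freqs), max(x$freqs), x$window[1], x$window[2]
  ))
  invisible(x)
}
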