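#' Epoched multichannel voltage container
#'
#' A lightweight container for item-locked voltage epochs: a numeric array
#' with dimensions items x channels x samples, the sampling rate, the time of
#' the first sample relative to item onset, and the width of the edge buffer
#' retained on each side for wavelet edge control.
#'
#' @param data Numeric array, items x channels x samples.
#' @param fs Sampling rate in samples per second.
#' @param t_start Time of the first sample in seconds relative to item onset
#'   (negative when the epoch starts before onset; the buffer is included).
#' @param buffer Buffer width in seconds present at each edge of the epoch.
#'   Buffer samples carry real signal but are excluded from analysis windows.
#' @param channels Character vector of channel labels, length `dim(data)[2]`.
#' @return An object of class `epoch_tensor`.
#' @export
epoch_tensor <- function(data, fs, t_start, buffer = 0, channels = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L, fs > 0, buffer >= 0)
  if (is.null(channels)) {
    channels <- dimnames(data)[[2]] %||% paste0("ch", seq_len(dim(data)[2]))
  }
  stopifnot(length(channels) == dim(data)[2])
  dimnames(data) <- list(NULL, channels, NULL)
  structure(
    list(
      data = data, fs = fs, t_start = t_start, buffer = buffer,
      channels = channels
    ),
    class = "epoch_tensor"
  )
}

#' @export
print.epoch_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_tensor> %d items x %d channels x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$fs
  ))
  cat(sprintf(
    "  time %0.3f .. %0.3f s re onset (buffer %0.3f s each side)\n",
    x$t_start, epoch_times(x)[d[3]], x$buffer
  ))
  invisible(x)
}

#' @export
dim.epoch_tensor <- function(x) dim(x$data)

#' Sample times of an epoch tensor
#'
#' @param epochs An [epoch_tensor()].
#' @return Numeric vector of sample times in seconds relative to item onset.
#' @export
epoch_times <- function(epochs) {
  epochs$t_start + (seq_len(dim(epochs$data)[3]) - 1L) / epochs$fs
}

# Index of samples whose times fall in [window[1], window[2]].
window_index <- function(epochs, window) {
  tt <- epoch_times(epochs)
  lo <- epochs$t_start + epochs$buffer
  hi <- tt[length(tt)] - epochs$buffer
  if (window[1] < lo - 1e-9 || window[2] > hi + 1e-9) {
    abort(sprintf(
      "Analysis window [%g, %g] s falls outside the buffered epoch [%g, %g] s.",
      window[1], window[2], lo, hi
    ))
  }
  which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
}

#' Subset an epoch tensor
#'
#' @param x An [epoch_tensor()].
#' @param items,channels Integer or (for channels) character indices; `NULL`
#'   keeps all.
#' @param ... Unused.
#' @export
subset.epoch_tensor <- function(x, items = NULL, channels = NULL, ...) {
  items <- items %||% seq_len(dim(x$data)[1])
  channels <- channels %||% x$channels
  if (is.character(channels)) channels <- match(channels, x$channels)
  epoch_tensor(
    x$data[items, channels, , drop = FALSE],
    fs = x$fs, t_start = x$t_start, buffer = x$buffer,
    channels = x$channels[channels]
  )
}
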