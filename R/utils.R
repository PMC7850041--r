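#' Logarithmically spaced frequency grid
#'
#' Frequencies spaced evenly on a log scale over a closed interval, the grid
#' used for wavelet decompositions throughout the package (20 wavelets on
#' 3--170 Hz for the subsequent-memory analysis, 8 on 3--180 Hz for the
#' classifier features).
#'
#' @param from,to Interval end points in Hz, both included in the grid.
#' @param n Number of frequencies.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' log_spaced_freqs(3, 170, 20)
log_spaced_freqs <- function(from, to, n) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

# Discrete Fourier frequencies (in Hz) for a length-n signal sampled at fs,
# in the order returned by stats::fft().
fft_freqs <- function(n, fs) {
  k <- c(seq(0L, floor(n / 2)), seq(-ceiling(n / 2) + 1L, -1L))
  k * fs / n
}

#' Vectorised Welch (unequal-variance) t-statistics
#'
#' Two-sample t-statistics with the Welch--Satterthwaite degrees of freedom,
#' computed column-wise so that a whole channel-by-frequency grid is
#' contrasted in one call. The sign convention is `x` minus `y`.
#'
#' @param x,y Numeric matrices with observations in rows and variables in
#'   columns (vectors are treated as single columns). Column counts must
#'   match.
#' @return A list with numeric vectors `t`, `df` and two-sided `p`, one entry
#'   per column.
#' @export
welch_t <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  n1 <- nrow(x)
  n2 <- nrow(y)
  if (n1 < 2L || n2 < 2L) {
    abort("welch_t() needs at least two observations in each group.")
  }
  m1 <- colMeans(x)
  m2 <- colMeans(y)
  v1 <- colSums(sweep(x, 2L, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(y, 2L, m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * pt(-abs(tt), df)
  list(t = unname(tt), df = unname(df), p = unname(p))
}

#' Receiver-operating-characteristic curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique predicted scores and
#' records the false/true positive rate at each, including the (0,0) and
#' (1,1) end points.
#'
#' @param scores Numeric vector of predicted scores (higher = more likely
#'   positive).
#' @param labels Logical or 0/1 vector of true class labels.
#' @return A tibble with columns `threshold`, `fpr`, `tpr`, ordered by
#'   increasing `fpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort("roc_curve() needs both classes present.")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # cumulative counts at each distinct threshold
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(l)[keep]
  fp <- cumsum(!l)[keep]
  tibble(
    threshold = c(Inf, s[keep]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the curve produced by [roc_curve()]. Equals the
#' Mann--Whitney U normalisation (probability that a random positive scores
#' above a random negative, ties counted half).
#'
#' @inheritParams roc_curve
#' @return A single number in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}

# Derive a stage seed from a root seed; keeps results < 2^31 and distinct
# across stages.
derive_seed <- function(seed, stage) {
  offsets <- c(
    behavior = 11L, eeg = 23L, cohort = 37L, connectivity = 53L,
    classifier = 71L, permutation = 89L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 101 + off) %% 2147483629)
}

# Shared input checks ---------------------------------------------------------

assert_events <- function(events, call = rlang::caller_env()) {
  needed <- c(
    "subject", "session", "task_variant", "list", "serial_position",
    "item", "category", "recalled", "output_position"
  )
  missing <- setdiff(needed, names(events))
  if (length(missing) > 0) {
    abort(
      paste0("Events table is missing columns: ", paste(missing, collapse = ", ")),
      call = call
    )
  }
  if (nrow(events) == 0) abort("Events table is empty.", call = call)
  bad <- xor(events$recalled, !is.na(events$output_position))
  if (any(bad)) {
    abort(
      paste0(
        "output_position must be present exactly for recalled items; ",
        sum(bad), " row(s) violate this."
      ),
      call = call
    )
  }
  invisible(events)
}

assert_electrodes <- function(electrodes, call = rlang::caller_env()) {
  needed <- c("channel", "region", "excluded")
  missing <- setdiff(needed, names(electrodes))
  if (length(missing) > 0) {
    abort(
      paste0("Electrode table is missing columns: ", paste(missing, collapse = ", ")),
      call = call
    )
  }
  if (anyDuplicated(electrodes$channel)) {
    abort("Electrode channel labels must be unique.", call = call)
  }
  invisible(electrodes)
}
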