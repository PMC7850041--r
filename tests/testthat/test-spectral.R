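# A tiny epoch tensor with known content: sinusoids + optional noise.
sine_epochs <- function(freq_hz, n_items = 3, n_channels = 2, fs = 500,
                        span = c(0, 1.4), buffer = 1, amplitude = 1,
                        phase = 0) {
  n <- round((diff(span) + 2 * buffer) * fs)
  tt <- (span[1] - buffer) + (seq_len(n) - 1) / fs
  x <- amplitude * sin(2 * pi * freq_hz * tt + phase)
  data <- array(rep(x, each = n_items * n_channels), dim = c(n_items, n_channels, n))
  epoch_tensor(data, fs = fs, t_start = tt[1], buffer = buffer)
}

test_that("the 60 Hz notch removes line noise and passes nothing through zero", {
  ep <- sine_epochs(60)
  el <- tibble::tibble(channel = ep$channels, region = "frontal", excluded = FALSE)
  out <- preprocess_epochs(ep, el)$epochs
  win <- epoch_times(out) >= 0 & epoch_times(out) <= 1.4
  ratio <- max(abs(out$data[1, 1, win])) / max(abs(ep$data[1, 1, win]))
  expect_lt(ratio, 0.05)
  # a 10 Hz tone far from the stopband is preserved
  ep10 <- sine_epochs(10)
  out10 <- preprocess_epochs(ep10, el)$epochs
  expect_gt(max(abs(out10$data[1, 1, win])) / max(abs(ep10$data[1, 1, win])), 0.95)
  # zero in, zero out
  ep0 <- ep
  ep0$data[] <- 0
  expect_equal(max(abs(preprocess_epochs(ep0, el)$epochs$data)), 0)
})

test_that("excluded channels are dropped and bipolar referencing differences neighbours", {
  ep <- sine_epochs(10, n_channels = 3)
  ep$data[, 2, ] <- 2 * ep$data[, 2, ] # make channels distinct
  el <- tibble::tibble(
    channel = ep$channels,
    region = c("frontal", "MTL", "LTC"),
    excluded = c(FALSE, FALSE, TRUE)
  )
  out <- preprocess_epochs(ep, el, reference = "bipolar", notch = FALSE)
  expect_equal(out$epochs$channels, "ch1-ch2")
  expect_equal(
    out$epochs$data[1, 1, ],
    ep$data[1, 1, ] - ep$data[1, 2, ],
    tolerance = 1e-12
  )
  # with reference = "none" the referencing step is the identity
  out2 <- preprocess_epochs(ep, el, reference = "none", notch = FALSE)
  expect_equal(out2$epochs$data, ep$data[, 1:2, , drop = FALSE], ignore_attr = TRUE)
})

test_that("Morlet power peaks at the stimulus frequency and scales quadratically", {
  ep <- sine_epochs(10, n_items = 1, n_channels = 1)
  pw <- morlet_power(ep, freqs = c(5, 10, 20), window = c(0.2, 1.2))
  mean_by_freq <- apply(pw$power[1, 1, , ], 1, mean)
  expect_equal(which.max(mean_by_freq), 2L)
  # doubling the amplitude quadruples pre-log power
  ep2 <- sine_epochs(10, n_items = 1, n_channels = 1, amplitude = 2)
  pw2 <- morlet_power(ep2, freqs = c(5, 10, 20), window = c(0.2, 1.2))
  expect_equal(pw2$power, 4 * pw$power, tolerance = 1e-9)
  # zero signal gives zero power
  ep0 <- ep
  ep0$data[] <- 0
  pw0 <- morlet_power(ep0, freqs = c(5, 10, 20), window = c(0.2, 1.2))
  expect_equal(max(pw0$power), 0)
  expect_error(morlet_power(ep, freqs = c(10, 300)), "Nyquist")
})

test_that("power features are z-scored within session per channel and frequency", {
  ds <- small_subject(seed = 3, n_lists = 4)
  feats <- encoding_power_features(ds$epochs, ds$events)
  m <- apply(feats$values, c(2, 3), mean)
  s <- apply(feats$values, c(2, 3), sd)
  expect_lt(max(abs(m)), 1e-6)
  expect_lt(max(abs(s - 1)), 1e-6)
})

test_that("degenerate feature variance maps to zero with a warning", {
  ep <- sine_epochs(10, n_items = 2, n_channels = 1)
  ev <- make_events(list(c(1, 2)), n_items = 2)
  expect_warning(
    feats <- encoding_power_features(ep, ev, freqs = c(5, 10)),
    "Constant power"
  )
  expect_equal(max(abs(feats$values)), 0)
})

test_that("single-item sessions are rejected for z-scoring", {
  ep <- sine_epochs(10, n_items = 1, n_channels = 1)
  ev <- make_events(list(c(1)), n_items = 1)
  expect_error(
    encoding_power_features(ep, ev, freqs = c(5, 10)),
    "single item"
  )
})

test_that("welch_t matches stats::t.test to 1e-10", {
  # the closed-form example
  res <- welch_t(c(2, 4, 6), c(1, 2, 3))
  ref <- t.test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  # identical classes give exactly zero
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # random matrices, column-wise
  set.seed(5)
  x <- matrix(rnorm(60), 10)
  y <- matrix(rnorm(48, sd = 2), 8)
  res2 <- welch_t(x, y)
  for (j in 1:6) {
    ref2 <- t.test(x[, j], y[, j])
    expect_equal(res2$t[j], unname(ref2$statistic), tolerance = 1e-10)
    expect_equal(res2$df[j], unname(ref2$parameter), tolerance = 1e-10)
  }
  expect_error(welch_t(1, c(1, 2)), "two observations")
})

test_that("BH correction matches an independent step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.2, 0.5, 0.9)
  expect_equal(p.adjust(p, method = "BH"), oracle_bh(p), tolerance = 1e-12)
  # every small p shares min_j p_j * m / j = 0.08 under step-up monotonicity
  expect_equal(oracle_bh(p)[1:5], rep(0.08, 5), tolerance = 1e-12)
  # BH fixed point: all p equal stay equal
  expect_equal(p.adjust(rep(0.001, 8), method = "BH"), rep(0.001, 8))
  set.seed(8)
  for (i in 1:10) {
    pr <- runif(sample(3:40, 1))
    expect_equal(p.adjust(pr, method = "BH"), oracle_bh(pr), tolerance = 1e-12)
  }
})
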