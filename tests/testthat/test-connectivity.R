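# Two-channel tensor with channel 2 a delayed copy of channel 1.
delayed_pair_epochs <- function(delay_s, n_items = 20, fs = 500,
                                span = c(0, 1.4), buffer = 1, f0 = 5,
                                noise_sd = 0) {
  n <- round((diff(span) + 2 * buffer) * fs)
  tt <- (span[1] - buffer) + (seq_len(n) - 1) / fs
  data <- array(0, dim = c(n_items, 2, n))
  set.seed(99)
  for (i in seq_len(n_items)) {
    ph <- runif(1, 0, 2 * pi)
    data[i, 1, ] <- sin(2 * pi * f0 * tt + ph) + rnorm(n, sd = noise_sd)
    data[i, 2, ] <- sin(2 * pi * f0 * (tt - delay_s) + ph) + rnorm(n, sd = noise_sd)
  }
  epoch_tensor(data, fs = fs, t_start = tt[1], buffer = buffer)
}

test_that("identical channels give zero phase difference and PLV 1", {
  ep <- delayed_pair_epochs(0)
  pd <- item_phase_difference(ep, c("ch1", "ch2"), freqs = 5)
  expect_lt(max(abs(pd)), 1e-8)
  plv <- plv_by_class(pd, recalled = rep(c(TRUE, FALSE), 10))
  expect_equal(plv$plv, rep(1, 2), tolerance = 1e-8)
})

test_that("a quarter-cycle delay at 5 Hz shows as a pi/2 phase difference", {
  ep <- delayed_pair_epochs(delay_s = 0.05) # quarter of a 5 Hz cycle
  pd <- item_phase_difference(ep, c("ch1", "ch2"), freqs = 5)
  expect_lt(max(abs(abs(pd) - pi / 2)), 0.05)
})

test_that("PLV extremes behave as defined", {
  # all phase differences equal -> PLV 1; antipodal pair -> PLV 0
  pd <- matrix(c(rep(0.7, 4)), ncol = 1)
  expect_equal(
    plv_by_class(pd, c(TRUE, TRUE, FALSE, FALSE))$plv, c(1, 1)
  )
  pd2 <- matrix(c(0, pi, 0, pi), ncol = 1)
  expect_equal(
    plv_by_class(pd2, c(TRUE, TRUE, FALSE, FALSE))$plv,
    c(0, 0),
    tolerance = 1e-12
  )
  # PLV is invariant to a constant phase offset on one channel
  set.seed(4)
  pd3 <- matrix(runif(40, -pi, pi), ncol = 2)
  labels <- rep(c(TRUE, FALSE), 10)
  expect_equal(
    plv_by_class(pd3, labels)$plv,
    plv_by_class(pd3 + 1.1, labels)$plv,
    tolerance = 1e-12
  )
})

test_that("random phases give the Rayleigh expectation E[PLV] ~ sqrt(pi)/2/sqrt(n)", {
  set.seed(12)
  n <- 40
  plvs <- replicate(400, {
    Mod(mean(exp(1i * runif(n, -pi, pi))))
  })
  expect_equal(mean(plvs), sqrt(pi) / 2 / sqrt(n), tolerance = 0.05)
})

test_that("permutation Z is deterministic given a seed and recovers injected synchrony", {
  cfg <- sim_config(n_lists = 8, n_channels = 6)
  tr <- effect_truth(sync_pairs = list(c("ch1", "ch4")), sync_plv_delta = 0.3)
  ds <- simulate_subject(cfg, tr, rng_seed = 61)
  net1 <- connectivity_sme_z(
    ds$epochs, ds$electrodes, ds$events$recalled,
    n_perm = 200, rng_seed = 5
  )
  net2 <- connectivity_sme_z(
    ds$epochs, ds$electrodes, ds$events$recalled,
    n_perm = 200, rng_seed = 5
  )
  expect_identical(net1$pair_z, net2$pair_z)
  pz <- net1$pair_z
  inj <- pz$ch_a == "ch1" & pz$ch_b == "ch4"
  expect_gt(pz$z[inj], max(quantile(pz$z[!inj], 0.95), 0))
})

test_that("more permutations stabilise the Z estimate", {
  ds <- small_subject(seed = 71, n_lists = 6, n_channels = 3)
  z_at <- function(n_perm, seed) {
    connectivity_sme_z(
      ds$epochs, ds$electrodes, ds$events$recalled,
      n_perm = n_perm, rng_seed = seed
    )$pair_z$z[1]
  }
  z100 <- vapply(1:8, function(s) z_at(100, s), numeric(1))
  z500 <- vapply(1:8, function(s) z_at(500, s), numeric(1))
  expect_lt(var(z500), var(z100))
})

test_that("ROI aggregation averages spanning pairs and thresholds edges", {
  net <- structure(
    list(
      pair_z = tibble::tibble(
        ch_a = c("c1", "c1", "c2"),
        ch_b = c("c2", "c3", "c3"),
        observed_sme = c(0.1, 0.2, 0.3),
        z = c(2.5, -0.5, 1.0)
      ),
      n_perm = 500, freqs = 4:8, window = c(0.4, 1.1)
    ),
    class = "theta_network"
  )
  el <- tibble::tibble(
    channel = c("c1", "c2", "c3"),
    region = c("frontal", "frontal", "MTL"),
    excluded = FALSE
  )
  edges <- roi_edges(net, el)
  expect_equal(
    edges$mean_z[edges$roi_a == "frontal" & edges$roi_b == "frontal"], 2.5
  )
  expect_equal(
    edges$mean_z[edges$roi_a == "MTL" | edges$roi_b == "MTL"],
    mean(c(-0.5, 1.0))
  )
  expect_equal(nrow(significant_edges(net)), 1)
  expect_equal(significant_edges(net)$z, 2.5)
})

test_that("group network statistics match direct t-tests", {
  set.seed(44)
  edge_tbl <- tidyr::expand_grid(
    subject = sprintf("s%02d", 1:10),
    roi_a = "frontal", roi_b = c("MTL", "parietal")
  )
  edge_tbl$mean_z <- rnorm(nrow(edge_tbl), mean = 0.5)
  groups <- tibble::tibble(
    subject = sprintf("s%02d", 1:10), group = rep(c("a", "b"), 5)
  )
  st <- network_group_stats(edge_tbl, groups)
  means_a <- st$subject_means$mean_edge[st$subject_means$group == "a"]
  ref <- t.test(means_a, mu = 0)
  got <- st$one_sample[st$one_sample$group == "a", ]
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  ref2 <- t.test(
    means_a, st$subject_means$mean_edge[st$subject_means$group == "b"]
  )
  expect_equal(st$two_sample$t, unname(ref2$statistic), tolerance = 1e-10)
})
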