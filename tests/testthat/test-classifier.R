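test_that("feature matrix has frequency-by-channel bookkeeping", {
  ds <- small_subject(seed = 23, n_lists = 3, n_channels = 10)
  x <- build_feature_matrix(ds$epochs, ds$events, ds$electrodes)
  expect_equal(ncol(x), 80) # 10 channels x 8 frequencies
  expect_equal(nrow(x), nrow(ds$events))
  info <- attr(x, "feature_info")
  expect_equal(nrow(info), 80)
  expect_equal(length(unique(info$channel)), 10)
  # z-scored per session: every column mean 0, sd 1
  expect_lt(max(abs(colMeans(x))), 1e-6)
  expect_lt(max(abs(apply(x, 2, sd) - 1)), 1e-6)
})

test_that("train_logreg minimises the stated penalized objective", {
  set.seed(10)
  n <- 60
  x <- matrix(rnorm(n * 3), n, 3)
  y <- runif(n) < plogis(x[, 1] - 0.5 * x[, 2])
  C <- 0.05
  fit <- train_logreg(x, y, C = C, balance = TRUE)
  expect_true(fit$converged)
  # independent numerical minimisation of the same objective
  s <- ifelse(y, n / (2 * sum(y)), n / (2 * sum(!y)))
  obj <- function(beta) {
    eta <- drop(cbind(x, 1) %*% beta)
    0.5 * sum(beta[1:3]^2) +
      C * sum(s * (log1p(exp(-abs(eta))) + pmax(eta, 0) - as.numeric(y) * eta))
  }
  ref <- optim(rep(0, 4), obj, method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  expect_equal(c(fit$weights, fit$intercept), ref$par, tolerance = 1e-5)
  expect_lte(obj(c(fit$weights, fit$intercept)), ref$value + 1e-8)
})

test_that("in the weak-penalty limit the fit approaches glm", {
  set.seed(11)
  n <- 200
  x <- matrix(rnorm(n * 2), n, 2)
  y <- runif(n) < plogis(0.8 * x[, 1])
  fit <- train_logreg(x, y, C = 1e6, balance = FALSE)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(
    c(fit$intercept, fit$weights),
    unname(coef(ref)),
    tolerance = 1e-4
  )
})

test_that("regularization shrinks weights and strengthens with smaller C", {
  set.seed(12)
  x <- matrix(rnorm(300), 100, 3)
  y <- runif(100) < plogis(x[, 1])
  w_weak <- train_logreg(x, y, C = 100)$weights
  w_med <- train_logreg(x, y, C = 0.01)$weights
  w_strong <- train_logreg(x, y, C = 2.4e-4)$weights
  expect_lt(sqrt(sum(w_med^2)), sqrt(sum(w_weak^2)))
  expect_lt(sqrt(sum(w_strong^2)), sqrt(sum(w_med^2)))
})

test_that("a separable 1-D toy recovers the effect direction", {
  set.seed(13)
  y <- rep(c(TRUE, FALSE), each = 30)
  x <- matrix(ifelse(y, 1, -1) + rnorm(60, sd = 0.2), ncol = 1)
  fit <- train_logreg(x, y, C = 2.4e-4)
  expect_gt(fit$weights[1], 0)
  expect_error(train_logreg(x, rep(TRUE, 60)), "Both classes")
})

test_that("balanced classes make the class weights a no-op", {
  set.seed(14)
  x <- matrix(rnorm(120), 60, 2)
  y <- rep(c(TRUE, FALSE), 30)
  fit_w <- train_logreg(x, y, C = 0.1, balance = TRUE)
  fit_u <- train_logreg(x, y, C = 0.1, balance = FALSE)
  expect_equal(fit_w$weights, fit_u$weights, tolerance = 1e-9)
  expect_equal(fit_w$intercept, fit_u$intercept, tolerance = 1e-9)
})

test_that("AUC equals the Mann-Whitney normalisation, ties included", {
  set.seed(15)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE) # many ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(
      auc(scores, labels),
      oracle_auc_mw(scores, labels),
      tolerance = 1e-10
    )
  }
  # perfectly informative scores give AUC 1
  expect_equal(auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
})

test_that("fold scheme follows the session/list structure", {
  ds <- small_subject(seed = 31, n_lists = 4)
  x <- build_feature_matrix(ds$epochs, ds$events, ds$electrodes)
  cv <- cross_validated_auc(x, ds$events$recalled, ds$events$session, ds$events$list)
  expect_equal(cv$fold_scheme, "leave-one-list-out")
  expect_equal(cv$n_folds, 4)
  # two sessions -> leave-one-session-out
  ses2 <- rep(c("ses01", "ses02"), length.out = nrow(ds$events))
  cv2 <- cross_validated_auc(x, ds$events$recalled, ses2, ds$events$list)
  expect_equal(cv2$fold_scheme, "leave-one-session-out")
  expect_equal(cv2$n_folds, 2)
  expect_error(
    cross_validated_auc(x, ds$events$recalled, rep("s", nrow(x)), rep(1, nrow(x))),
    "two sessions or two lists"
  )
})

test_that("out-of-fold predictions never see their own labels (no leakage)", {
  ds <- small_subject(seed = 37, n_lists = 5)
  x <- build_feature_matrix(ds$epochs, ds$events, ds$electrodes)
  y <- ds$events$recalled
  cv <- cross_validated_auc(x, y, ds$events$session, ds$events$list)
  # flip the labels inside list 3 only: predictions for list 3 items are
  # produced by models trained on the other lists, so they cannot change
  y2 <- y
  y2[ds$events$list == 3] <- !y2[ds$events$list == 3]
  cv2 <- cross_validated_auc(x, y2, ds$events$session, ds$events$list)
  in3 <- cv$predictions$fold == "3"
  expect_equal(
    cv$predictions$probability[in3],
    cv2$predictions$probability[cv2$predictions$fold == "3"],
    tolerance = 1e-12
  )
})

test_that("a strongly informative generator yields high AUC and small permutation p", {
  ds <- small_subject(
    seed = 41, n_lists = 8,
    truth = effect_truth(hfa_power_delta = 1, theta_power_delta = -0.5)
  )
  x <- build_feature_matrix(ds$epochs, ds$events, ds$electrodes)
  perm <- auc_permutation_pvalue(
    x, ds$events$recalled, ds$events$session, ds$events$list,
    n_perm = 100, rng_seed = 2
  )
  expect_gt(perm$observed_auc, 0.8)
  expect_lte(perm$perm_p, 0.01 + 1e-12) # best attainable at n_perm = 100 is ~0.0099
  # determinism of the permutation p-value
  perm2 <- auc_permutation_pvalue(
    x, ds$events$recalled, ds$events$session, ds$events$list,
    n_perm = 100, rng_seed = 2
  )
  expect_identical(perm$perm_p, perm2$perm_p)
  expect_warning(
    auc_permutation_pvalue(
      x, ds$events$recalled, ds$events$session, ds$events$list,
      n_perm = 50, rng_seed = 2
    ),
    "coarse"
  )
})
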