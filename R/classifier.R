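#' Spectral feature matrix for recall classification
#'
#' Average Morlet log power over the item encoding epoch (0--1.366 s after
#' onset) at eight frequencies log-spaced on 3--180 Hz, for every analysed
#' channel, z-scored over items within each session per feature. Columns are
#' ordered frequency-within-channel.
#'
#' @param epochs An [epoch_tensor()] aligned 1:1 with `events` rows.
#' @param events Events tibble (provides sessions and recall labels).
#' @param electrodes Optional electrode tibble; excluded channels are
#'   dropped.
#' @param freqs Frequency grid; default `log_spaced_freqs(3, 180, 8)`.
#' @param window Averaging window in seconds.
#' @param z_score Z-score within session (default TRUE).
#' @return A numeric matrix items x (channels * frequencies) with an
#'   attribute `feature_info` tibble (`channel`, `frequency`).
#' @export
build_feature_matrix <- function(epochs, events, electrodes = NULL,
                                 freqs = log_spaced_freqs(3, 180, 8),
                                 window = c(0, 1.366),
                                 z_score = TRUE) {
  if (!is.null(electrodes)) {
    assert_electrodes(electrodes)
    keep <- electrodes$channel[!electrodes$excluded]
    if (!all(keep %in% epochs$channels)) {
      abort("Electrode table names channels missing from the epochs.")
    }
    epochs <- subset(epochs, channels = keep)
  }
  feats <- encoding_power_features(
    epochs, events,
    freqs = freqs, window = window, z_score = z_score
  )
  d <- dim(feats$values)
  x <- matrix(aperm(feats$values, c(1, 3, 2)), nrow = d[1]) # freq fastest, then channel
  attr(x, "feature_info") <- tidyr::expand_grid(
    channel = feats$channels, frequency = freqs
  )
  x
}

#' L2-penalized logistic regression
#'
#' Fits logistic regression minimising
#' `0.5 * ||w||^2 + C * sum_i s_i * log(1 + exp(-y_i (x_i w + b)))`
#' by Newton iteration, with the intercept unpenalized. `C` is the
#' inverse-regularization parameter (smaller = stronger penalty); the
#' default 2.4e-4 is the cross-validated value used for spectral recall
#' classifiers. With `balance = TRUE` each observation carries the weight
#' `n_total / (2 * n_class)` of its class, so the minority class counts in
#' inverse proportion to its frequency.
#'
#' @param x Numeric feature matrix, items x features.
#' @param y Logical (or 0/1) outcome vector.
#' @param C Inverse-regularization strength.
#' @param balance Apply inverse-class-frequency observation weights.
#' @param tol,max_iter Newton convergence controls.
#' @return A list of class `logreg_fit`: `weights`, `intercept`, `C`,
#'   `converged`, `n_iter`.
#' @export
train_logreg <- function(x, y, C = 2.4e-4, balance = TRUE,
                         tol = 1e-10, max_iter = 100) {
  x <- as.matrix(x)
  y <- as.logical(y)
  stopifnot(nrow(x) == length(y), C > 0)
  if (all(y) || all(!y)) abort("Both classes must be present to fit.")
  n <- nrow(x)
  s <- if (balance) {
    ifelse(y, n / (2 * sum(y)), n / (2 * sum(!y)))
  } else {
    rep(1, n)
  }
  t01 <- as.numeric(y)
  xa <- cbind(x, 1) # intercept last, unpenalized
  p_dim <- ncol(xa)
  pen <- c(rep(1, p_dim - 1L), 0)
  beta <- numeric(p_dim)
  obj_old <- Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(xa %*% beta)
    p <- plogis(eta)
    # objective (log1p(exp(.)) stable form)
    ll <- sum(s * (log1p(exp(-abs(eta))) + pmax(eta, 0) - t01 * eta))
    obj <- 0.5 * sum(pen * beta^2) + C * ll
    grad <- pen * beta + C * drop(crossprod(xa, s * (p - t01)))
    w <- pmax(s * p * (1 - p), 1e-12)
    hess <- C * crossprod(xa * sqrt(w)) + diag(pen, p_dim)
    step <- solve(hess, grad)
    beta <- beta - step
    if (abs(obj_old - obj) < tol * (abs(obj) + 1) && max(abs(grad)) < 1e-6) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  structure(
    list(
      weights = beta[-p_dim], intercept = beta[p_dim], C = C,
      balance = balance, converged = converged, n_iter = iter
    ),
    class = "logreg_fit"
  )
}

#' @export
#' @rdname train_logreg
#' @param object A `logreg_fit`.
#' @param newdata Feature matrix to score.
#' @param ... Unused.
predict.logreg_fit <- function(object, newdata, ...) {
  plogis(drop(as.matrix(newdata) %*% object$weights) + object$intercept)
}

#' Cross-validated recall classification
#'
#' Trains the penalized logistic classifier with leave-one-session-out folds
#' for multi-session subjects and leave-one-list-out folds for
#' single-session subjects, pools the out-of-fold predicted probabilities,
#' and computes the ROC curve and its trapezoidal AUC (chance 0.50).
#'
#' @param x Feature matrix, items x features (e.g. [build_feature_matrix()]).
#' @param y Logical recall labels per item.
#' @param sessions,lists Session and list identifiers per item, defining the
#'   fold structure.
#' @param C Inverse-regularization strength.
#' @param balance Inverse-class-frequency observation weights.
#' @return An object of class `classifier_result`: `auc`, `roc` tibble,
#'   `fold_scheme`, `predictions` tibble (`item_index`, `fold`,
#'   `probability`, `recalled`), `C`, `n_folds`, and `skipped_folds` (folds
#'   left unpredicted because their training data had one class).
#' @export
cross_validated_auc <- function(x, y, sessions, lists, C = 2.4e-4,
                                balance = TRUE) {
  x <- as.matrix(x)
  y <- as.logical(y)
  n <- nrow(x)
  stopifnot(length(y) == n, length(sessions) == n, length(lists) == n)
  if (length(unique(sessions)) >= 2) {
    fold <- as.character(sessions)
    scheme <- "leave-one-session-out"
  } else if (length(unique(lists)) >= 2) {
    fold <- as.character(lists)
    scheme <- "leave-one-list-out"
  } else {
    abort("Cross-validation needs at least two sessions or two lists.")
  }
  folds <- unique(fold)
  prob <- rep(NA_real_, n)
  skipped <- character(0)
  for (f in folds) {
    test <- fold == f
    ytr <- y[!test]
    if (all(ytr) || all(!ytr)) {
      skipped <- c(skipped, f)
      next
    }
    fit <- train_logreg(x[!test, , drop = FALSE], ytr, C = C, balance = balance)
    prob[test] <- predict(fit, x[test, , drop = FALSE])
  }
  if (length(skipped) > 0) {
    warn(paste0(
      "Folds skipped (single-class training data): ",
      paste(skipped, collapse = ", ")
    ))
  }
  ok <- !is.na(prob)
  if (!any(y[ok]) || all(y[ok])) {
    abort("Pooled predictions cover a single class; AUC undefined.")
  }
  structure(
    list(
      auc = auc(prob[ok], y[ok]),
      roc = roc_curve(prob[ok], y[ok]),
      fold_scheme = scheme,
      predictions = tibble(
        item_index = which(ok), fold = fold[ok],
        probability = prob[ok], recalled = y[ok]
      ),
      C = C, n_folds = length(folds), skipped_folds = skipped
    ),
    class = "classifier_result"
  )
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf(
    "<classifier_result> %s: AUC = %.3f over %d folds (C = %g)\n",
    x$fold_scheme, x$auc, x$n_folds, x$C
  ))
  invisible(x)
}

#' Permutation significance of a cross-validated AUC
#'
#' Re-runs the full cross-validation with the recall labels randomly
#' permuted (class sizes preserved) `n_perm` times and returns
#' `p = (1 + #\{null AUC >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams cross_validated_auc
#' @param n_perm Number of label permutations (default 1000; fewer than 100
#'   draws a warning).
#' @param rng_seed Integer seed for the permutation sequence.
#' @return A list with `observed_auc`, `perm_p`, and the vector `null_auc`.
#' @export
auc_permutation_pvalue <- function(x, y, sessions, lists, C = 2.4e-4,
                                   balance = TRUE, n_perm = 1000,
                                   rng_seed = 1) {
  if (n_perm < 100) warn("n_perm < 100 gives a coarse permutation p-value.")
  obs <- cross_validated_auc(x, y, sessions, lists, C = C, balance = balance)
  set.seed(as.integer(rng_seed))
  null_auc <- vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    cross_validated_auc(x, yp, sessions, lists, C = C, balance = balance)$auc
  }, numeric(1))
  list(
    observed_auc = obs$auc,
    perm_p = (1 + sum(null_auc >= obs$auc)) / (n_perm + 1),
    null_auc = null_auc
  )
}
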