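# Independent oracle implementations and fixture builders shared by the
# tests. These deliberately re-derive each statistic from its definition by
# plain enumeration, staying independent of the package's vectorised code
# paths.

# Build a one-subject events table from explicit recall sequences.
# recalls: list with one integer vector per study list, giving the serial
# positions in recall order. categories: optional list of per-item category
# vectors (length n_items each).
make_events <- function(recalls, n_items = 12, categories = NULL,
                        subject = "s01", session = "ses01",
                        task_variant = if (is.null(categories)) "unrelated" else "categorized") {
  out <- lapply(seq_along(recalls), function(li) {
    rec <- recalls[[li]]
    stopifnot(!anyDuplicated(rec), all(rec %in% seq_len(n_items)))
    op <- rep(NA_integer_, n_items)
    op[rec] <- seq_along(rec)
    tibble::tibble(
      subject = subject, session = session, task_variant = task_variant,
      list = li, serial_position = seq_len(n_items),
      item = sprintf("%s_l%02d_w%02d", subject, li, seq_len(n_items)),
      category = if (is.null(categories)) NA_integer_ else as.integer(categories[[li]]),
      recalled = !is.na(op), output_position = op
    )
  })
  dplyr::bind_rows(out)
}

# Brute-force temporal clustering score for one recall sequence: walk the
# transitions, enumerate candidate distances explicitly.
oracle_temporal_list <- function(recall_order, n_items) {
  scores <- c()
  recalled <- recall_order[1]
  for (k in seq_len(length(recall_order) - 1)) {
    prev <- recall_order[k]
    nxt <- recall_order[k + 1]
    candidates <- setdiff(seq_len(n_items), recalled)
    others <- setdiff(candidates, nxt)
    if (length(others) > 0) {
      farther <- 0
      tied <- 0
      for (o in others) {
        if (abs(o - prev) > abs(nxt - prev)) farther <- farther + 1
        if (abs(o - prev) == abs(nxt - prev)) tied <- tied + 1
      }
      scores <- c(scores, (farther + 0.5 * tied) / length(others))
    }
    recalled <- c(recalled, nxt)
  }
  if (length(scores) == 0) NA_real_ else mean(scores)
}

# ARC for one list from the definition, enumerating adjacent pairs.
oracle_arc <- function(cats_in_recall_order) {
  n <- length(cats_in_recall_order)
  if (n < 2) return(NA_real_)
  r_obs <- 0
  for (i in seq_len(n - 1)) {
    if (cats_in_recall_order[i] == cats_in_recall_order[i + 1]) r_obs <- r_obs + 1
  }
  tab <- table(cats_in_recall_order)
  e_r <- sum(tab * (tab - 1)) / n
  max_r <- n - length(tab)
  if (abs(max_r - e_r) < 1e-12) return(NA_real_)
  (r_obs - e_r) / (max_r - e_r)
}

# Benjamini-Hochberg step-up from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  q[ord] <- p[ord] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in rev(seq_len(m - 1))) {
    q[ord[i]] <- min(q[ord[i]], q[ord[i + 1]])
  }
  pmin(q, 1)
}

# AUC as the Mann-Whitney U normalisation via ranks (ties averaged).
oracle_auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small standard simulated subject reused across tests.
small_subject <- function(seed = 11, n_lists = 6, n_channels = 4,
                          truth = memsig::effect_truth()) {
  memsig::simulate_subject(
    memsig::sim_config(n_lists = n_lists, n_channels = n_channels),
    truth,
    rng_seed = seed
  )
}
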