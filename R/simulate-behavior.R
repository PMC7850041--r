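#' Simulate free-recall behaviour for one subject
#'
#' Draws recall outcomes and recall order for every list of every session of
#' one simulated subject. Each item is recalled with its serial-position
#' probability; the recall order is then produced by a sequential sampler
#' whose next-recall weights decay exponentially with the absolute
#' serial-position lag from the just-recalled item and carry a multiplicative
#' bonus for same-category items, so that temporal and semantic clustering
#' span chance (strengths 0) to perfect (large strengths).
#'
#' The returned table contains only scored lists: the practice list of a
#' session is never generated, matching analyses that exclude it.
#'
#' @param config A [sim_config()].
#' @param truth An [effect_truth()].
#' @param rng_seed Integer seed; identical seeds give identical tables.
#' @param subject Subject identifier stored in the table.
#' @return An events tibble with one row per studied item: `subject`,
#'   `session`, `task_variant`, `list`, `serial_position`, `item`,
#'   `category` (NA for the unrelated variant), `recalled`,
#'   `output_position` (NA unless recalled).
#' @export
#' @examples
#' ev <- simulate_behavior(sim_config(n_lists = 3), effect_truth(), rng_seed = 1)
#' dplyr::count(ev, list, recalled)
simulate_behavior <- function(config, truth, rng_seed, subject = "s01") {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "effect_truth"))
  set.seed(as.integer(rng_seed))
  sessions <- map(seq_len(config$n_sessions), function(ses) {
    lists <- map(seq_len(config$n_lists), function(li) {
      simulate_list(config, truth, subject, ses, li)
    })
    list_rbind(lists)
  })
  list_rbind(sessions)
}

# One 12-item list: category layout, recall flags, recall order.
simulate_list <- function(config, truth, subject, session, list_idx) {
  n <- config$items_per_list
  categories <- if (config$task_variant == "categorized") {
    categorized_layout()
  } else {
    rep(NA_integer_, n)
  }
  recalled <- runif(n) < truth$recall_base
  order_out <- sample_recall_order(
    recalled, categories,
    tau = truth$temporal_clustering_strength,
    sem = truth$semantic_clustering_strength
  )
  output_position <- rep(NA_integer_, n)
  output_position[order_out] <- seq_along(order_out)
  item_ids <- sprintf("%s_s%02d_l%02d_w%02d", subject, session, list_idx, seq_len(n))
  tibble(
    subject = subject,
    session = sprintf("ses%02d", session),
    task_variant = config$task_variant,
    list = list_idx,
    serial_position = seq_len(n),
    item = item_ids,
    category = categories,
    recalled = recalled,
    output_position = output_position
  )
}

# Category sequence for a categorized list: 3 categories x 4 exemplars as six
# successive same-category pairs, adjacent pairs from distinct categories.
categorized_layout <- function() {
  repeat {
    pairs <- sample(rep(1:3, each = 2))
    if (all(diff(pairs) != 0)) break
  }
  rep(pairs, each = 2)
}

# Sequential softmax sampler over not-yet-recalled items. Weights:
# exp(-|lag| * tau) * exp(sem * same_category); the first recall uses
# exp(-(pos - 1) * tau) so large tau degenerates to study order.
sample_recall_order <- function(recalled, categories, tau, sem) {
  pool <- which(recalled)
  if (length(pool) == 0L) return(integer(0))
  out <- integer(length(pool))
  logw0 <- -(pool - 1) * tau
  out[1] <- pool[sample_softmax(logw0)]
  remaining <- setdiff(pool, out[1])
  for (k in seq_len(length(pool) - 1L)) {
    prev <- out[k]
    logw <- -abs(remaining - prev) * tau
    if (!is.na(categories[1])) {
      logw <- logw + sem * (categories[remaining] == categories[prev])
    }
    out[k + 1] <- remaining[sample_softmax(logw)]
    remaining <- setdiff(remaining, out[k + 1])
  }
  out
}

sample_softmax <- function(logw) {
  if (length(logw) == 1L) return(1L)
  w <- exp(logw - max(logw))
  sample.int(length(w), 1L, prob = w)
}
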