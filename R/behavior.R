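#' Serial-position curve
#'
#' Probability of recall at each list position, per subject, with an optional
#' group summary (mean and standard error across subjects per position).
#'
#' @param events Events tibble (see [simulate_behavior()] for the schema).
#' @param groups Optional tibble with columns `subject`, `group`; when given,
#'   a `group_summary` attribute holding per-group mean +/- SE per position is
#'   attached.
#' @return A tibble with `subject`, `serial_position`, `n_presented`,
#'   `n_recalled`, `p_recall`.
#' @export
serial_position_curve <- function(events, groups = NULL) {
  assert_events(events)
  spc <- events |>
    summarise(
      n_presented = n(),
      n_recalled = sum(.data$recalled),
      .by = c("subject", "serial_position")
    ) |>
    mutate(p_recall = .data$n_recalled / .data$n_presented) |>
    arrange(.data$subject, .data$serial_position)
  if (!is.null(groups)) {
    gs <- spc |>
      inner_join(groups, by = "subject") |>
      summarise(
        mean_p = mean(.data$p_recall),
        se_p = sd(.data$p_recall) / sqrt(n()),
        n_subjects = n(),
        .by = c("group", "serial_position")
      )
    attr(spc, "group_summary") <- gs
  }
  spc
}

#' Temporal clustering score of recall transitions
#'
#' For each within-list recall transition, the absolute serial-position lag
#' to the next recalled item is percentile-ranked against the lags to every
#' item of that list not yet recalled: the score for a transition is the
#' fraction of the other available items lying strictly farther than the one
#' actually recalled, plus half the fraction at a tied distance. A subject's
#' score is the mean over all their transitions; 1.0 means every transition
#' went to the nearest available neighbour and 0.5 is chance.
#'
#' Transitions with no alternative available item are skipped (their
#' percentile is undefined). Items never recalled still count as available
#' until the recall sequence ends.
#'
#' @param events Events tibble.
#' @return A tibble with `subject`, `temporal_score`, `n_transitions`;
#'   `temporal_score` is `NA` for subjects with no scorable transition.
#' @export
temporal_clustering_score <- function(events) {
  assert_events(events)
  events |>
    group_by(.data$subject) |>
    group_modify(function(df, key) {
      sc <- df |>
        group_by(.data$session, .data$list) |>
        group_map(~ list_transition_percentiles(.x)) |>
        unlist()
      tibble(
        temporal_score = if (length(sc)) mean(sc) else NA_real_,
        n_transitions = length(sc)
      )
    }) |>
    ungroup()
}

# Percentile scores for all transitions of one list.
list_transition_percentiles <- function(df) {
  rec <- df[!is.na(df$output_position), ]
  if (nrow(rec) < 2L) return(numeric(0))
  order_pos <- rec$serial_position[order(rec$output_position)]
  all_pos <- df$serial_position
  out <- numeric(0)
  recalled_so_far <- order_pos[1]
  for (k in seq_len(length(order_pos) - 1L)) {
    prev <- order_pos[k]
    nxt <- order_pos[k + 1]
    avail <- setdiff(all_pos, recalled_so_far) # excludes prev, includes nxt
    others <- setdiff(avail, nxt)
    if (length(others) > 0L) {
      d_others <- abs(others - prev)
      d_actual <- abs(nxt - prev)
      out <- c(out, (sum(d_others > d_actual) + 0.5 * sum(d_others == d_actual)) /
        length(others))
    }
    recalled_so_far <- c(recalled_so_far, nxt)
  }
  out
}

#' Semantic clustering: adjusted ratio of clustering (ARC)
#'
#' For each categorized list, counts observed same-category adjacent recall
#' pairs R and normalises against chance: ARC = (R - E(R)) / (maxR - E(R)),
#' with E(R) = sum over categories of n_i (n_i - 1) / N for n_i recalled
#' exemplars of category i among N recalls, and maxR = N - k for k categories
#' recalled. 1 is maximal category clustering; 0 is chance. Lists where
#' maxR = E(R) (fewer than 2 recalls, or all recalls from one category) are
#' skipped. A subject's score is the mean over their defined lists.
#'
#' @param events Events tibble; only `task_variant == "categorized"` rows are
#'   scored (an error if none).
#' @return A tibble with `subject`, `arc_score`, `n_lists` (lists entering
#'   the mean).
#' @export
semantic_arc_score <- function(events) {
  assert_events(events)
  ev <- filter(events, .data$task_variant == "categorized")
  if (nrow(ev) == 0) abort("No categorized-task events to score.")
  if (anyNA(ev$category)) abort("Categorized events must carry category labels.")
  ev |>
    group_by(.data$subject) |>
    group_modify(function(df, key) {
      arcs <- df |>
        group_by(.data$session, .data$list) |>
        group_map(~ list_arc(.x)) |>
        unlist()
      arcs <- arcs[!is.na(arcs)]
      tibble(
        arc_score = if (length(arcs)) mean(arcs) else NA_real_,
        n_lists = length(arcs)
      )
    }) |>
    ungroup()
}

# ARC for one list; NA when degenerate.
list_arc <- function(df) {
  rec <- df[!is.na(df$output_position), ]
  n_total <- nrow(rec)
  if (n_total < 2L) return(NA_real_)
  cats <- rec$category[order(rec$output_position)]
  r_obs <- sum(cats[-1] == cats[-n_total])
  n_i <- table(cats)
  e_r <- sum(n_i * (n_i - 1)) / n_total
  max_r <- n_total - length(n_i)
  if (abs(max_r - e_r) < 1e-12) return(NA_real_)
  (r_obs - e_r) / (max_r - e_r)
}

#' Mixed-effects group contrasts on recall performance
#'
#' Fits linear mixed-effects models (maximum likelihood) on the per-item 0/1
#' recall outcome with group, task variant and serial position as fixed
#' effects and a random intercept per subject, and returns likelihood-ratio
#' chi-square tests (1 df each) for (a) the main effect of group and (b) the
#' group-by-task interaction.
#'
#' @param events Events tibble covering at least two subjects per group.
#' @param groups Tibble with columns `subject`, `group` (two levels).
#' @return A tibble with one row per test: `term` (`"group"`,
#'   `"group:task"`), `chisq`, `df`, `p_value`, `converged`. The interaction
#'   row is `NA` when only one task variant is present.
#' @export
recall_group_lr_test <- function(events, groups) {
  assert_events(events)
  d <- inner_join(events, groups, by = "subject") |>
    mutate(
      recalled_num = as.numeric(.data$recalled),
      serial_position = factor(.data$serial_position),
      group = factor(.data$group),
      task_variant = factor(.data$task_variant)
    )
  if (nlevels(d$group) < 2) abort("Both groups must be present.")
  n_per <- d |> distinct(.data$subject, .data$group) |> count(.data$group)
  if (any(n_per$n < 2)) abort("Each group needs at least two subjects.")
  two_tasks <- nlevels(d$task_variant) >= 2

  fit <- function(formula) {
    ok <- TRUE
    m <- withCallingHandlers(
      lme4::lmer(formula, data = d, REML = FALSE),
      warning = function(w) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      }
    )
    list(model = m, converged = ok)
  }

  if (two_tasks) {
    m_base <- fit(recalled_num ~ task_variant + serial_position + (1 | subject))
    m_grp <- fit(recalled_num ~ group + task_variant + serial_position + (1 | subject))
    m_int <- fit(recalled_num ~ group * task_variant + serial_position + (1 | subject))
    a_grp <- anova(m_base$model, m_grp$model)
    a_int <- anova(m_grp$model, m_int$model)
    tibble(
      term = c("group", "group:task"),
      chisq = c(a_grp$Chisq[2], a_int$Chisq[2]),
      df = c(a_grp$Df[2], a_int$Df[2]),
      p_value = c(a_grp$`Pr(>Chisq)`[2], a_int$`Pr(>Chisq)`[2]),
      converged = c(
        m_base$converged && m_grp$converged,
        m_grp$converged && m_int$converged
      )
    )
  } else {
    m_base <- fit(recalled_num ~ serial_position + (1 | subject))
    m_grp <- fit(recalled_num ~ group + serial_position + (1 | subject))
    a_grp <- anova(m_base$model, m_grp$model)
    tibble(
      term = c("group", "group:task"),
      chisq = c(a_grp$Chisq[2], NA_real_),
      df = c(a_grp$Df[2], NA_real_),
      p_value = c(a_grp$`Pr(>Chisq)`[2], NA_real_),
      converged = c(m_base$converged && m_grp$converged, NA)
    )
  }
}

#' Welch group comparison of per-subject clustering scores
#'
#' Two-sample unequal-variance t-test between groups on a per-subject score
#' column, the comparison used for temporal and semantic clustering scores.
#'
#' @param scores Tibble with `subject` and the score column.
#' @param groups Tibble with `subject`, `group`.
#' @param score_col Name of the score column.
#' @return One-row tibble: `t`, `df`, `p_value`, group means.
#' @export
clustering_group_test <- function(scores, groups, score_col) {
  d <- inner_join(scores, groups, by = "subject")
  d <- d[!is.na(d[[score_col]]), ]
  gl <- sort(unique(d$group))
  if (length(gl) != 2) abort("Exactly two groups are required.")
  x <- d[[score_col]][d$group == gl[1]]
  y <- d[[score_col]][d$group == gl[2]]
  ht <- t.test(x, y)
  tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_1 = mean(x), mean_2 = mean(y), group_1 = gl[1], group_2 = gl[2]
  )
}
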