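test_that("serial-position curve counts recalls per position", {
  # all recalled
  ev <- make_events(list(1:12, 1:12))
  spc <- serial_position_curve(ev)
  expect_equal(spc$p_recall, rep(1, 12))
  # none recalled
  ev0 <- make_events(list(integer(0)))
  spc0 <- serial_position_curve(ev0)
  expect_equal(spc0$p_recall, rep(0, 12))
  # position 1 recalled in 1 of 2 lists
  ev05 <- make_events(list(c(1), integer(0)))
  spc05 <- serial_position_curve(ev05)
  expect_equal(spc05$p_recall[spc05$serial_position == 1], 0.5)
  expect_error(serial_position_curve(ev[0, ]), "empty")
})

test_that("serial-position curve attaches a group summary when asked", {
  ev <- dplyr::bind_rows(
    make_events(list(1:12), subject = "a"),
    make_events(list(c(1, 2)), subject = "b")
  )
  groups <- tibble::tibble(subject = c("a", "b"), group = c("g1", "g2"))
  spc <- serial_position_curve(ev, groups = groups)
  gs <- attr(spc, "group_summary")
  expect_equal(nrow(gs), 24)
  expect_equal(gs$mean_p[gs$group == "g1"], rep(1, 12))
})

test_that("perfect study-order recall scores exactly 1", {
  ev <- make_events(list(1:12))
  expect_identical(temporal_clustering_score(ev)$temporal_score, 1)
})

test_that("temporal score matches the worked 4-item example", {
  # studied 1-2-3-4, recalled 1, 4, 2: both transitions go to the farthest
  # available item, so each scores 0 and the subject scores 0
  ev <- make_events(list(c(1, 4, 2)), n_items = 4)
  res <- temporal_clustering_score(ev)
  expect_equal(res$temporal_score, 0)
  expect_equal(res$n_transitions, 2L)
})

test_that("temporal score agrees exactly with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:60) {
    n_items <- sample(3:6, 1)
    k <- sample(2:n_items, 1)
    rec <- sample(n_items, k)
    ev <- make_events(list(rec), n_items = n_items)
    expect_equal(
      temporal_clustering_score(ev)$temporal_score,
      oracle_temporal_list(rec, n_items),
      tolerance = 1e-12
    )
  }
})

test_that("subjects with no scorable transition get a missing score", {
  ev <- make_events(list(c(3), integer(0)))
  res <- temporal_clustering_score(ev)
  expect_true(is.na(res$temporal_score))
  expect_equal(res$n_transitions, 0L)
})

test_that("ARC is 1 for perfectly category-blocked recall", {
  cats <- rep(1:3, each = 4)
  ev <- make_events(list(1:12), categories = list(cats))
  expect_equal(semantic_arc_score(ev)$arc_score, 1)
})

test_that("ARC matches the worked A,A,B,B,C,C example", {
  # 6 recalls in category order A,A,B,B,C,C: R = 3, E(R) = 1, maxR = 3
  cats <- c(1, 1, 2, 2, 3, 3, 1, 1, 2, 2, 3, 3)
  ev <- make_events(list(1:6), categories = list(cats))
  expect_equal(semantic_arc_score(ev)$arc_score, 1)
  # a non-extreme case against the enumeration oracle: recall order mixes
  rec <- c(1, 3, 2, 5, 4, 6)
  ev2 <- make_events(list(rec), categories = list(cats))
  expect_equal(
    semantic_arc_score(ev2)$arc_score,
    oracle_arc(cats[rec]),
    tolerance = 1e-12
  )
})

test_that("ARC is invariant to category relabeling and ignores item identity", {
  set.seed(7)
  cats <- rep(1:3, each = 4)[sample(12)]
  rec <- sample(12, 7)
  ev <- make_events(list(rec), categories = list(cats))
  relab <- c(2L, 3L, 1L)[cats]
  ev2 <- make_events(list(rec), categories = list(relab))
  ev3 <- ev
  ev3$item <- paste0("renamed_", ev3$item)
  expect_equal(semantic_arc_score(ev)$arc_score, semantic_arc_score(ev2)$arc_score)
  expect_equal(semantic_arc_score(ev)$arc_score, semantic_arc_score(ev3)$arc_score)
})

test_that("degenerate lists are excluded from the ARC mean", {
  cats <- rep(1:3, each = 4)
  ev <- make_events(
    list(1:4, 1:12), # first list: all recalls one category -> maxR = E(R)
    categories = list(cats, cats)
  )
  res <- semantic_arc_score(ev)
  expect_equal(res$n_lists, 1L)
  expect_equal(res$arc_score, 1)
})

test_that("mixed-model group test detects an injected recall deficit", {
  cfg <- sim_config(n_lists = 8)
  base <- default_recall_base()
  subs <- lapply(1:12, function(i) {
    tr <- if (i <= 6) {
      effect_truth(recall_base = pmax(base - 0.18, 0))
    } else {
      effect_truth()
    }
    simulate_behavior(cfg, tr, rng_seed = 400 + i, subject = sprintf("s%02d", i))
  })
  ev <- dplyr::bind_rows(subs)
  groups <- tibble::tibble(
    subject = sprintf("s%02d", 1:12),
    group = rep(c("case", "control"), each = 6)
  )
  res <- recall_group_lr_test(ev, groups)
  expect_equal(res$term, c("group", "group:task"))
  expect_lt(res$p_value[res$term == "group"], 0.05)
  expect_true(is.na(res$chisq[res$term == "group:task"])) # single task variant
  expect_error(
    recall_group_lr_test(ev, dplyr::mutate(groups, group = "case")),
    "Both groups"
  )
})

test_that("interaction test detects a deficit confined to the categorized task", {
  cfg_u <- sim_config(n_lists = 6, task_variant = "unrelated")
  cfg_c <- sim_config(n_lists = 6, task_variant = "categorized")
  base <- default_recall_base()
  subs <- lapply(1:16, function(i) {
    case <- i <= 8
    tr_u <- effect_truth()
    tr_c <- if (case) effect_truth(recall_base = pmax(base - 0.22, 0)) else effect_truth()
    dplyr::bind_rows(
      simulate_behavior(cfg_u, tr_u, rng_seed = 900 + i, subject = sprintf("s%02d", i)),
      simulate_behavior(cfg_c, tr_c, rng_seed = 950 + i, subject = sprintf("s%02d", i)) |>
        dplyr::mutate(session = "ses02")
    )
  })
  ev <- dplyr::bind_rows(subs)
  groups <- tibble::tibble(
    subject = sprintf("s%02d", 1:16),
    group = rep(c("case", "control"), each = 8)
  )
  res <- recall_group_lr_test(ev, groups)
  expect_lt(res$p_value[res$term == "group:task"], 0.05)
})

test_that("clustering group comparison uses Welch's t-test", {
  scores <- tibble::tibble(
    subject = sprintf("s%02d", 1:10),
    temporal_score = c(0.61, 0.64, 0.58, 0.66, 0.62, 0.55, 0.54, 0.57, 0.52, 0.56)
  )
  groups <- tibble::tibble(
    subject = sprintf("s%02d", 1:10),
    group = rep(c("a", "b"), each = 5)
  )
  res <- clustering_group_test(scores, groups, "temporal_score")
  ref <- t.test(scores$temporal_score[1:5], scores$temporal_score[6:10])
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-12)
})
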