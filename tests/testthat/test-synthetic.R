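test_that("blocked lists present each category as one contiguous block", {
  cfg <- experiment_config(n_participants = 6, seed = 1)
  lists <- build_lists(cfg, "blocked", seed = 10)
  expect_equal(nrow(lists), 40L)
  runs <- rle(lists$category)
  expect_equal(length(runs$lengths), 5L)
  expect_true(all(runs$lengths == 8L))
  expect_equal(length(unique(lists$word)), 40L)
})

test_that("randomized lists respect the run-length constraint and reuse all words", {
  cfg <- experiment_config(n_participants = 6, seed = 1)
  lists <- build_lists(cfg, "randomized", seed = 10)
  expect_equal(nrow(lists), 40L)
  expect_lte(max(rle(lists$category)$lengths), 3L)
  expect_equal(length(unique(lists$word)), 40L)
  expect_identical(build_lists(cfg, "randomized", seed = 7),
                   build_lists(cfg, "randomized", seed = 7))
})

test_that("degenerate configurations are caught", {
  cfg1 <- experiment_config(n_participants = 2, n_categories = 1, seed = 1)
  expect_equal(length(rle(build_lists(cfg1, "blocked", 1)$category)$lengths),
               1L)
  expect_error(build_lists(cfg1, "randomized", 1), "unsatisfiable")
  expect_error(experiment_config(n_participants = 0), "participant")
  expect_error(experiment_config(item_jol_mean = 120), "0-100")
  expect_error(experiment_config(list_jol_means = c(blocked = 9,
                                                    randomized = 4)), "0-8")
  expect_error(experiment_config(clustering_weight = 2), "clustering_weight")
})

test_that("JOL draws respect their scales and collapse when spread is zero", {
  cfg <- experiment_config(n_participants = 6, seed = 1)
  item <- simulate_jols(cfg, "item", "blocked", n = 500, seed = 3)
  expect_true(all(item >= 0 & item <= 100))
  expect_true(all(item == as.integer(item)))
  lst <- simulate_jols(cfg, "list", "randomized", n = 500, seed = 4)
  expect_true(all(lst >= 0 & lst <= 8))
  cfg0 <- experiment_config(n_participants = 6, item_jol_sd = 0,
                            list_jol_sds = c(blocked = 0, randomized = 0),
                            seed = 1)
  expect_true(all(simulate_jols(cfg0, "item", "blocked", 50, seed = 5) == 50))
  expect_true(all(simulate_jols(cfg0, "list", "blocked", 50, seed = 5) ==
                    round(4.89)))
})

test_that("perfect verbatim parameters produce recall of every item on every test", {
  cfg <- experiment_config(n_participants = 6, seed = 2)
  lists <- build_lists(cfg, "blocked", seed = 1)
  out <- simulate_recall(lists, params_named(1, 0, 0.5, 0.5, 0.5, 0.5),
                         clustering_weight = 0.5, seed = 9)
  expect_true(all(out$recalled_t1 & out$recalled_t2 & out$recalled_t3))
  for (t in 1:3) {
    expect_setequal(out[[paste0("output_position_t", t)]], 1:40)
  }
})

test_that("the clustering weight spans uniform output to perfect contiguity", {
  cfg <- experiment_config(n_participants = 6, seed = 3)
  lists <- build_lists(cfg, "randomized", seed = 2)
  p <- params_named(0.6, 0.05, 0.8, 0.8, 0.8, 0.6)
  full <- simulate_recall(lists, p, clustering_weight = 1, seed = 11)
  ord <- order(full$output_position_t1)
  ord <- ord[!is.na(full$output_position_t1[ord])]
  expect_equal(arc(full$category[ord])$arc, 1)

  # with zero weight the output order is a uniform permutation of the
  # recalled items, so observed repetitions match the chance expectation
  # E(R) on average (ARC itself has mean slightly off 0 under the null
  # because its above/below-chance denominators differ)
  dev <- withr::with_seed(21, {
    vapply(1:300, function(i) {
      out <- simulate_recall(lists, p, clustering_weight = 0,
                             seed = sample.int(1e8, 1))
      o <- order(out$output_position_t1)
      o <- o[!is.na(out$output_position_t1[o])]
      labs <- out$category[o]
      count_repetitions(labs) - expected_repetitions(labs)
    }, numeric(1))
  })
  expect_lt(abs(mean(dev)), 3 * stats::sd(dev) / sqrt(length(dev)))
})

test_that("a generated experiment honors the design contract and is reproducible", {
  cfg <- experiment_config(n_participants = 36, seed = 99)
  trials <- generate_experiment(cfg)
  expect_equal(nrow(trials), 36L * 40L)
  per_cell <- dplyr::count(trials, organization, jol_condition)
  expect_equal(nrow(per_cell), 6L)
  expect_true(all(per_cell$n == 6L * 40L))
  # flag-presence rules: item_jol iff item cell; list_jol iff list cell,
  # attached to list-final rows
  expect_true(all(is.na(trials$item_jol[trials$jol_condition != "item"])))
  expect_true(all(!is.na(trials$item_jol[trials$jol_condition == "item"])))
  expect_true(all(is.na(trials$list_jol[trials$jol_condition != "list"])))
  lj <- trials[trials$jol_condition == "list", ]
  expect_true(all(!is.na(lj$list_jol[lj$serial_position %% 8 == 0])))
  expect_true(all(is.na(lj$list_jol[lj$serial_position %% 8 != 0])))
  # recalled flags consistent with output positions
  for (t in 1:3) {
    expect_identical(trials[[paste0("recalled_t", t)]],
                     !is.na(trials[[paste0("output_position_t", t)]]))
  }
  expect_identical(trials, generate_experiment(cfg))
})

test_that("aggregated synthetic cells recover their generating parameters", {
  # round trip generator -> pattern counts -> estimation, one cell at the
  # default cell size (40 participants x 40 items)
  truth <- default_true_params()[["randomized.none"]]
  biases <- withr::with_seed(17, {
    vapply(1:10, function(i) {
      cts <- simulate_patterns(truth, 1600, seed = sample.int(1e8, 1))
      fit <- drm_fit(cts, n_starts = 3, seed = sample.int(1e8, 1))
      unclass(fit$estimates) - unclass(truth)[names(fit$estimates)]
    }, numeric(6))
  })
  expect_true(all(abs(rowMeans(biases)) < 0.05))
})
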