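test_that("responses are normalized, spelling-corrected and intrusions logged", {
  study <- c("apple", "pear", "grape")
  sc <- score_recall(c("Apple ", "aple", "zebra"), study)
  # "Apple " matches exactly after normalization; "aple" cannot re-match the
  # consumed "apple" and is no closer than distance 1 to any other study
  # word, so it joins "zebra" as an intrusion
  expect_true(sc$recalled[sc$word == "apple"])
  expect_equal(sc$output_position[sc$word == "apple"], 1L)
  expect_false(sc$recalled[sc$word == "pear"])
  expect_setequal(attr(sc, "intrusions"), c("aple", "zebra"))

  sc2 <- score_recall("aple", study)
  expect_true(sc2$recalled[sc2$word == "apple"])   # edit distance 1
  expect_false(any(score_recall("aple", study, tolerance = 0)$recalled))

  # duplicates collapse; ties go to the first-listed study word
  sc3 <- score_recall(c("pear", "pear"), study)
  expect_equal(sum(sc3$recalled), 1L)
  sc4 <- score_recall("cab", c("cat", "car"))  # distance 1 to both
  expect_true(sc4$recalled[sc4$word == "cat"])
  expect_false(sc4$recalled[sc4$word == "car"])

  expect_error(score_recall("x", character()), "empty")
})

test_that("scoring flags are order-insensitive even though positions change", {
  study <- c("dog", "cat", "horse", "mouse")
  responses <- c("cat", "dog", "mouse")
  base <- score_recall(responses, study)
  perm <- score_recall(rev(responses), study)
  expect_identical(base$recalled, perm$recalled)
  expect_false(identical(base$output_position, perm$output_position))
})

test_that("clean transcripts scored at tolerance 0 reproduce generator ground truth", {
  cfg <- experiment_config(n_participants = 12, seed = 5)
  trials <- generate_experiment(cfg)
  transcripts <- purrr::list_rbind(purrr::map(unique(trials$participant_id),
    function(pid) {
      df <- trials[trials$participant_id == pid, ]
      purrr::list_rbind(purrr::map(1:3, function(t) {
        pos <- df[[paste0("output_position_t", t)]]
        rec <- df[!is.na(pos), ]
        if (!nrow(rec)) return(NULL)
        tibble::tibble(participant_id = pid, test = t,
                       response_order = sort(pos[!is.na(pos)]),
                       response = rec$word[order(pos[!is.na(pos)])])
      }))
    }))
  study_lists <- trials[, c("participant_id", "organization", "jol_condition",
                            "list_index", "serial_position", "word",
                            "category")]
  scored <- score_transcripts(transcripts, study_lists, tolerance = 0)
  for (t in 1:3) {
    expect_identical(scored[[paste0("recalled_t", t)]],
                     trials[[paste0("recalled_t", t)]])
    expect_identical(scored[[paste0("output_position_t", t)]],
                     trials[[paste0("output_position_t", t)]])
  }
})

test_that("patterns aggregate to cell counts that sum to participants x items", {
  cfg <- experiment_config(n_participants = 12, seed = 6)
  trials <- generate_experiment(cfg)
  counts <- build_patterns(trials)
  expect_equal(sum(counts$count), nrow(trials))
  sums <- dplyr::summarise(dplyr::group_by(counts, condition),
                           n = sum(count))
  expect_true(all(sums$n == 2L * 40L))  # 2 participants per cell here
  # explicit pattern example: recalled on tests 1 and 2 only -> CCE, index 6
  one <- tibble::tibble(recalled_t1 = TRUE, recalled_t2 = TRUE,
                        recalled_t3 = FALSE)
  pc <- build_patterns(one, by = character())
  expect_equal(pc$count[pc$pattern == "CCE"], 1L)
  expect_equal(pc$index[pc$pattern == "CCE"], 6L)
  expect_error(build_patterns(tibble::tibble(x = 1)), "recall flag")
})

test_that("the outlier screen is upper-sided and anchored at the cell median", {
  cell <- tibble::tibble(
    participant_id = 1:5, organization = "randomized", jol_condition = "item",
    mean_recall = c(0.3, 0.32, 0.35, 0.33, 0.95))
  # type-7 quartiles of the five values: Q1 = .32, median = .33, Q3 = .35;
  # threshold = .33 + 1.5 * .03 = .375, so only .95 is excluded
  res <- outlier_filter(cell)
  expect_identical(res$included[res$mean_recall == 0.95], FALSE)
  expect_equal(sum(res$included), 4L)
  expect_equal(nrow(attr(res, "exclusions")), 1L)

  flat <- dplyr::mutate(cell, mean_recall = 0.4)
  expect_true(all(outlier_filter(flat)$included))

  low <- dplyr::mutate(cell, mean_recall = c(0.3, 0.32, 0.35, 0.33, 0.01))
  expect_true(all(outlier_filter(low)$included))          # rule as printed
  expect_equal(sum(outlier_filter(low, symmetric = TRUE)$included), 4L)

  tiny <- cell[1:3, ]
  expect_warning(res3 <- outlier_filter(tiny), "fewer than 4")
  expect_true(all(res3$included))
})
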