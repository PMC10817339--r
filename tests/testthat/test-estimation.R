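test_that("G-squared matches hand-evaluated values and edge conventions", {
  # perfect fit
  p <- params_named(0.4, 0.1, 0.5, 0.5, 0.5, 0.5)
  pr <- pattern_prob_vector(p)
  expect_equal(g_squared(1000 * pr, pr), 0)
  # two-cell reductions, hand evaluation: 2(60 ln 1.2 + 40 ln 0.8)
  expect_equal(g_squared(c(60, 40), c(0.5, 0.5)),
               2 * (60 * log(1.2) + 40 * log(0.8)), tolerance = 1e-12)
  expect_equal(g_squared(c(60, 40), c(0.5, 0.5)), 4.0271, tolerance = 1e-4)
  # all mass in one of two equiprobable cells: 200 ln 2
  expect_equal(g_squared(c(100, 0), c(0.5, 0.5)), 200 * log(2))
  expect_equal(g_squared(c(100, 0), c(0.5, 0.5)), 138.629, tolerance = 1e-3)
  # zero expected probability with observed mass
  expect_warning(gs <- g_squared(c(5, 5), c(1, 0)), "infinite")
  expect_identical(gs, Inf)
})

test_that("fitting exact expected counts recovers the generating parameters", {
  truth <- params_named(0.4, 0.1, 0.6, 0.6, 0.6, 0.5)
  pr <- pattern_prob_vector(truth)
  fit <- drm_fit(10000 * pr, n_starts = 10, seed = 2)
  expect_true(fit$converged)
  expect_lt(fit$g_squared, 1e-4)
  expect_equal(fit$df, 1L)
  expect_true(all(abs(unclass(fit$estimates) -
                        unclass(truth)[names(fit$estimates)]) < 1e-3))
})

test_that("estimates recover interior truth from large simulated samples", {
  truth <- params_named(0.4, 0.1, 0.5, 0.6, 0.7, 0.5)
  cts <- simulate_patterns(truth, 1e5, seed = 8)
  fit <- drm_fit(cts, n_starts = 10, seed = 3)
  expect_true(all(abs(unclass(fit$estimates) -
                        unclass(truth)[names(fit$estimates)]) < 0.01))
})

test_that("the fitted optimum dominates random parameter vectors", {
  cts <- simulate_patterns(params_named(0.4, 0.1, 0.5, 0.6, 0.7, 0.5),
                           2000, seed = 12)
  obs <- stats::setNames(cts$count, cts$pattern)
  fit <- drm_fit(obs, n_starts = 10, seed = 4)
  expect_gte(fit$g_squared, 0)
  for (p in random_params(50, seed = 21)) {
    expect_lte(fit$g_squared, g_squared(obs, pattern_prob_vector(p)) + 1e-8)
  }
})

test_that("degenerate all-error data yields a flagged boundary fit", {
  obs <- c(EEE = 200, EEC = 0, ECE = 0, ECC = 0, CEE = 0, CEC = 0, CCE = 0,
           CCC = 0)
  expect_warning(fit <- drm_fit(obs, n_starts = 5, seed = 1), "boundary")
  expect_true(fit$boundary)
  expect_lt(fit$estimates[["D"]], 0.01)
})

test_that("equality test is null for identical conditions and rejects unknown parameters", {
  cts <- simulate_patterns(params_named(0.4, 0.06, 0.5, 0.6, 0.8, 0.2),
                           1600, seed = 31)
  lt <- drm_lr_test(cts, cts, "J1", n_starts = 5, seed = 2)
  expect_lte(lt$delta_g_squared, 1e-4)
  expect_equal(lt$df, 1L)
  expect_error(drm_lr_test(cts, cts, "Q"), "unknown model parameter")
})

test_that("delta-G-squared p-values are uniform under the null", {
  # asymptotic uniformity, checked at a sample size where the chi-square(1)
  # reference applies; at small experiment-scale samples the test is mildly
  # anticonservative, which the type-I band check covers separately
  pv <- null_lr_pvalues(n_rep = 1000, n_items = 2000)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("condition battery fits every cell and runs the paired comparisons", {
  p <- params_named(0.4, 0.06, 0.5, 0.6, 0.8, 0.2)
  long <- purrr::list_rbind(purrr::map(
    c("blocked.item", "blocked.none", "randomized.item", "randomized.none"),
    function(cond) {
      dplyr::mutate(simulate_patterns(p, 800,
                                      seed = nchar(cond) + match(cond,
                                        c("blocked.item", "blocked.none",
                                          "randomized.item",
                                          "randomized.none"))),
                    condition = cond)
    }))
  bat <- fit_conditions(long, n_starts = 3, seed = 5)
  expect_equal(nrow(bat$fits), 4L)
  expect_setequal(names(bat$fits)[2:7], c("D", "F", "J1", "J2", "J3", "R"))
  # item vs none within each organization, all six parameters
  expect_equal(nrow(bat$comparisons), 2 * 6)
  expect_true(all(bat$comparisons$delta_g_squared >= 0))
  expect_true(all(bat$comparisons$p_value >= 0 & bat$comparisons$p_value <= 1))

  single <- fit_conditions(dplyr::mutate(simulate_patterns(p, 400, seed = 2),
                                         condition = "only"),
                           n_starts = 3, seed = 6)
  expect_equal(nrow(single$fits), 1L)
  expect_equal(nrow(single$comparisons), 0L)
  expect_error(fit_conditions(tibble::tibble()), "trial-level|empty|must")
})

test_that("tidiers expose estimates and fit summaries as tibbles", {
  cts <- simulate_patterns(params_named(0.4, 0.1, 0.5, 0.6, 0.7, 0.5),
                           1000, seed = 17)
  fit <- drm_fit(cts, n_starts = 3, seed = 1)
  td <- generics::tidy(fit)
  expect_identical(td$parameter, c("D", "F", "J1", "J2", "J3", "R"))
  gl <- generics::glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(all(c("g_squared", "df", "p_value", "converged") %in% names(gl)))
})
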