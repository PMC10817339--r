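# Independent oracles used across the suite. These deliberately avoid the
# package's likelihood code paths.

# Enumeration oracle: walk every latent path (branch x forgetting outcomes x
# familiarity outcomes) and accumulate path probabilities into the 8 recall
# patterns. Returns a named 8-vector in canonical order EEE ... CCC.
enum_pattern_probs <- function(params) {
  p <- unclass(params)
  D <- p[["D"]]; Fg <- p[["F"]]; R <- p[["R"]]
  J <- c(p[["J1"]], p[["J2"]], p[["J3"]])
  lev <- recall_patterns()$pattern
  out <- stats::setNames(numeric(8), lev)
  pat <- function(b) paste(ifelse(b, "C", "E"), collapse = "")
  # verbatim branch: recalled while in the direct-access state; the state is
  # lost after test 1 (prob F) or, having survived, after test 2 (prob F)
  out[pat(c(TRUE, FALSE, FALSE))] <- out[pat(c(TRUE, FALSE, FALSE))] + D * Fg
  out[pat(c(TRUE, TRUE, FALSE))] <-
    out[pat(c(TRUE, TRUE, FALSE))] + D * (1 - Fg) * Fg
  out[pat(c(TRUE, TRUE, TRUE))] <-
    out[pat(c(TRUE, TRUE, TRUE))] + D * (1 - Fg) * (1 - Fg)
  # gist branch: every combination of the three familiarity outcomes
  for (o1 in c(TRUE, FALSE)) for (o2 in c(TRUE, FALSE)) for (o3 in c(TRUE, FALSE)) {
    b <- c(o1, o2, o3)
    pr <- prod(ifelse(b, J, 1 - J))
    out[pat(b)] <- out[pat(b)] + (1 - D) * R * pr
  }
  # null branch
  out["EEE"] <- out["EEE"] + (1 - D) * (1 - R)
  out
}

# Random valid parameter vectors (uniform over the unit hypercube).
random_params <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      v <- stats::runif(6)
      drm_params(direct_access = v[1], forgetting = v[2],
                 reconstruction = v[3], familiarity_t1 = v[4],
                 familiarity_t2 = v[5], familiarity_t3 = v[6])
    })
  })
}

# Monte-Carlo permutation oracle for the expected number of adjacent
# same-category repetitions: mean and standard error over uniform shuffles.
mc_expected_reps <- function(counts, n_shuffle, seed) {
  labels <- rep(seq_along(counts), counts)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffle), function(i) {
      s <- sample(labels)
      sum(s[-1] == s[-length(s)])
    }, numeric(1))
  })
  c(mean = mean(reps), se = stats::sd(reps) / sqrt(n_shuffle))
}

# Null sampling distribution of the delta-G-squared equality test: two
# conditions drawn from the same parameters, the named parameter tested.
# Cached so the calibration and uniformity checks share one simulation.
.null_sim_cache <- new.env(parent = emptyenv())
null_lr_pvalues <- function(n_rep = 2000, n_items = 320, seed = 20240105) {
  key <- paste(n_rep, n_items, seed, sep = "_")
  if (!is.null(.null_sim_cache[[key]])) return(.null_sim_cache[[key]])
  p0 <- drm_params(direct_access = 0.33, forgetting = 0.06,
                   reconstruction = 0.15, familiarity_t1 = 0.34,
                   familiarity_t2 = 0.58, familiarity_t3 = 0.84)
  pv <- withr::with_seed(seed, {
    vapply(seq_len(n_rep), function(i) {
      sds <- sample.int(.Machine$integer.max - 1L, 3)
      a <- simulate_patterns(p0, n_items, seed = sds[1])
      b <- simulate_patterns(p0, n_items, seed = sds[2])
      drm_lr_test(a, b, "J1", n_starts = 2, seed = sds[3])$p_value
    }, numeric(1))
  })
  .null_sim_cache[[key]] <- pv
  pv
}

# Named parameter vector shorthand used throughout the tests.
params_named <- function(D, F, J1, J2, J3, R) {
  drm_params(direct_access = D, forgetting = F, reconstruction = R,
             familiarity_t1 = J1, familiarity_t2 = J2, familiarity_t3 = J3)
}
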