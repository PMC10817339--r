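#' G-squared goodness-of-fit statistic
#'
#' Likelihood-ratio statistic `2 * sum(O * log(O / (n * pi)))` comparing
#' observed multinomial counts to expected cell probabilities. Empty cells
#' contribute 0 (`0 * log 0 := 0`); expected probabilities are floored at
#' 1e-12 inside the logarithm only. An expected probability of zero paired
#' with a positive observed count yields `Inf` with a warning.
#'
#' @param observed Observed counts: a numeric vector, or a pattern-count
#'   tibble as returned by [simulate_patterns()].
#' @param expected_probs Expected cell probabilities: a numeric vector of the
#'   same length, or a tibble as returned by [pattern_probabilities()].
#' @return The non-negative statistic (scalar); 0 iff observed proportions
#'   match the expected probabilities on all non-empty cells.
#' @examples
#' g_squared(c(60, 40), c(0.5, 0.5))
#' @export
g_squared <- function(observed, expected_probs) {
  if (is.data.frame(observed)) observed <- as_pattern_counts(observed)
  if (is.data.frame(expected_probs)) expected_probs <- expected_probs$probability
  observed <- as.numeric(observed)
  expected_probs <- as.numeric(expected_probs)
  stopifnot(length(observed) == length(expected_probs),
            all(observed >= 0), all(expected_probs >= 0))
  n <- sum(observed)
  if (n <= 0) stop("total observed count must be positive", call. = FALSE)
  if (any(expected_probs == 0 & observed > 0)) {
    warning("observed count in a cell with expected probability 0; ",
            "G-squared is infinite")
    return(Inf)
  }
  pos <- observed > 0
  2 * sum(observed[pos] *
            log(observed[pos] / (n * pmax(expected_probs[pos], 1e-12))))
}

#' Critical value for the G-squared fit test
#'
#' The model's goodness of fit is judged against the chi-square distribution
#' with `df` degrees of freedom (asymptotic null of G-squared); for the
#' single-condition dual-retrieval fit, `df = 8 - 1 - 6 = 1` and the critical
#' value at `alpha = 0.05` is 3.84.
#'
#' @param alpha Significance level.
#' @param df Degrees of freedom.
#' @export
gsq_critical <- function(alpha = 0.05, df = 1) {
  stats::qchisq(alpha, df = df, lower.tail = FALSE)
}

# ---- likelihood machinery -------------------------------------------------

# Pattern-space constants, canonical index order (EEE ... CCC); precomputed
# because the likelihood and its gradient sit inside the optimizer's hot loop.
.pat_idx <- 0:7
.pat_c <- cbind(t1 = .pat_idx %/% 4L == 1L,
                t2 = (.pat_idx %/% 2L) %% 2L == 1L,
                t3 = .pat_idx %% 2L == 1L)
.i_eee <- 1L; .i_cee <- 5L; .i_cce <- 7L; .i_ccc <- 8L

# Pattern probabilities and their 8 x 6 Jacobian at theta = (D,F,J1,J2,J3,R).
# pi = D*V + (1-D)*R*B + (1-D)*(1-R)*e_EEE with
#   V = verbatim kernel (CCC: (1-F)^2, CCE: (1-F)F, CEE: F),
#   B = independent-Bernoulli gist kernel over (J1,J2,J3).
model_pieces <- function(theta, jacobian = FALSE) {
  D <- theta[1]; Fg <- theta[2]; J <- theta[3:5]; R <- theta[6]
  b1 <- ifelse(.pat_c[, 1], J[1], 1 - J[1])
  b2 <- ifelse(.pat_c[, 2], J[2], 1 - J[2])
  b3 <- ifelse(.pat_c[, 3], J[3], 1 - J[3])
  B <- b1 * b2 * b3
  V <- numeric(8)
  V[.i_ccc] <- (1 - Fg)^2
  V[.i_cce] <- (1 - Fg) * Fg
  V[.i_cee] <- Fg
  eE <- numeric(8); eE[.i_eee] <- 1
  pi <- D * V + (1 - D) * R * B + (1 - D) * (1 - R) * eE
  if (!jacobian) return(list(pi = pi))
  dV <- numeric(8)
  dV[.i_ccc] <- -2 * (1 - Fg)
  dV[.i_cce] <- 1 - 2 * Fg
  dV[.i_cee] <- 1
  Jac <- matrix(0, 8, 6)
  Jac[, 1] <- V - R * B - (1 - R) * eE                    # d/dD
  Jac[, 2] <- D * dV                                      # d/dF
  for (t in 1:3) {                                        # d/dJt
    Jac[, 2 + t] <- (1 - D) * R * B *
      (.pat_c[, t] - J[t]) / (J[t] * (1 - J[t]))
  }
  Jac[, 6] <- (1 - D) * (B - eE)                          # d/dR
  list(pi = pi, jac = Jac)
}

# Negative multinomial log-likelihood (up to the data-only constant) and its
# gradient, for one condition's 8-vector of counts.
make_nll <- function(counts) {
  fn <- function(theta) {
    pi <- model_pieces(theta)$pi
    -sum(counts * log(pmax(pi, 1e-12)))
  }
  gr <- function(theta) {
    mp <- model_pieces(theta, jacobian = TRUE)
    w <- counts / pmax(mp$pi, 1e-12)
    -as.numeric(t(mp$jac) %*% w)
  }
  list(fn = fn, gr = gr)
}

# Stratified (Latin hypercube) random starts plus the fixed midpoint start,
# in [lb, ub]^k.
make_starts <- function(n_starts, k, seed, lb = 1e-6, ub = 1 - 1e-6) {
  starts <- matrix(0.5, 1, k)
  if (n_starts > 0) {
    lh <- withr::with_seed(seed, lhs::randomLHS(n_starts, k))
    starts <- rbind(starts, lb + (ub - lb) * lh)
  }
  starts
}

# Run L-BFGS-B from every start; return the best optimum. Ties in the
# objective (within 1e-9) are broken by the lexicographically smaller
# parameter vector.
multistart_optim <- function(fn, gr, starts, lb = 1e-6, ub = 1 - 1e-6) {
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], fn, gr, method = "L-BFGS-B",
                   lower = lb, upper = ub,
                   # tight relative tolerance so nested fits agree to ~1e-7
                   # in the deviance even at thousands of items
                   control = list(factr = 1e5, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value - 1e-9 ||
        (abs(res$value - best$value) <= 1e-9 &&
         lexicographically_smaller(res$par, best$par))) {
      best <- res
    }
  }
  if (is.null(best)) {
    stop("all optimizer starts failed (", nrow(starts), " attempted)",
         call. = FALSE)
  }
  best$n_ok <- n_ok
  best
}

lexicographically_smaller <- function(a, b) {
  d <- a - b
  i <- which(abs(d) > 0)[1]
  !is.na(i) && d[i] < 0
}

#' Fit the dual-retrieval model to pattern counts
#'
#' Maximum-likelihood estimation of the six dual-retrieval parameters from the
#' observed frequencies of the 8 three-test recall patterns of one condition.
#' The multinomial log-likelihood is maximized over `[1e-6, 1 - 1e-6]^6` by
#' bounded quasi-Newton (L-BFGS-B with analytic gradients) from `n_starts`
#' stratified random starts plus a fixed midpoint start. Goodness of fit is
#' the G-squared statistic on `df = 8 - 1 - 6 = 1`, referred to chi-square(1).
#'
#' @param observed Pattern counts: a tibble with `pattern` and `count` columns
#'   (e.g. from [simulate_patterns()] or [build_patterns()]), a named
#'   8-vector, or a bare 8-vector in canonical index order.
#' @param n_starts Number of stratified random starts (default 20).
#' @param seed Integer seed for the random starts.
#' @return A `drm_fit` object with elements `estimates` ([drm_params()]),
#'   `g_squared`, `df`, `p_value`, `log_likelihood`, `converged`,
#'   `n_starts_used`, `boundary`, `observed`, `n_items`, `fitted_probs`.
#'   [generics::tidy()] returns the parameter table and [generics::glance()]
#'   the fit summary.
#' @examples
#' counts <- simulate_patterns(drm_params(0.4, 0.1, 0.5, 0.5, 0.6, 0.7),
#'                             n_items = 2000, seed = 7)
#' fit <- drm_fit(counts, n_starts = 5, seed = 1)
#' generics::glance(fit)
#' @export
drm_fit <- function(observed, n_starts = 20, seed = 1) {
  counts <- as_pattern_counts(observed)
  n <- sum(counts)
  if (n < 1) stop("at least one non-zero cell is required", call. = FALSE)
  obj <- make_nll(counts)
  starts <- make_starts(n_starts, 6, seed)
  best <- multistart_optim(obj$fn, obj$gr, starts)
  theta <- stats::setNames(best$par, drm_param_names())
  fitted <- model_pieces(best$par)$pi
  gsq <- g_squared(counts, fitted)
  boundary <- any(theta <= 1e-6 + 1e-4) || any(theta >= 1 - 1e-6 - 1e-4)
  if (boundary && counts[["EEE"]] == n) {
    warning("all observed mass in EEE; estimates lie on the boundary")
  }
  structure(list(
    estimates = structure(theta, class = "drm_params"),
    g_squared = gsq,
    df = 1L,
    p_value = stats::pchisq(gsq, df = 1, lower.tail = FALSE),
    log_likelihood = -best$value + saturated_ll_const(counts),
    converged = best$convergence == 0,
    n_starts_used = best$n_ok,
    boundary = boundary,
    observed = counts,
    n_items = n,
    fitted_probs = stats::setNames(fitted, pattern_levels())
  ), class = "drm_fit")
}

# log multinomial coefficient: the data-only constant of the log-likelihood
saturated_ll_const <- function(counts) {
  lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
}

#' @export
print.drm_fit <- function(x, digits = 3, ...) {
  cat("<dual-retrieval model fit>  n =", x$n_items, "items\n")
  print(round(unclass(x$estimates), digits))
  cat(sprintf("G2(%d) = %.3f, p = %.3f%s\n", x$df, x$g_squared, x$p_value,
              if (x$boundary) "  [boundary estimate]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.drm_fit <- function(x, ...) {
  tibble::tibble(parameter = drm_param_names(),
                 estimate = as.numeric(x$estimates[drm_param_names()]))
}

#' @exportS3Method generics::glance
glance.drm_fit <- function(x, ...) {
  tibble::tibble(g_squared = x$g_squared, df = x$df, p_value = x$p_value,
                 log_likelihood = x$log_likelihood, n_items = x$n_items,
                 converged = x$converged, boundary = x$boundary,
                 n_starts_used = x$n_starts_used)
}

# ---- cross-condition equality tests ---------------------------------------

# Joint constrained negative log-likelihood: one parameter equated across two
# conditions, all others free per condition. theta = (shared, other5_a,
# other5_b), 11 free parameters.
make_joint_nll <- function(counts_a, counts_b, which_par) {
  j <- match(which_par, drm_param_names())
  free <- setdiff(1:6, j)
  expand <- function(theta, cond) {
    full <- numeric(6)
    full[j] <- theta[1]
    full[free] <- if (cond == 1) theta[2:6] else theta[7:11]
    full
  }
  nll_a <- make_nll(counts_a); nll_b <- make_nll(counts_b)
  fn <- function(theta) {
    nll_a$fn(expand(theta, 1)) + nll_b$fn(expand(theta, 2))
  }
  gr <- function(theta) {
    ga <- nll_a$gr(expand(theta, 1)); gb <- nll_b$gr(expand(theta, 2))
    c(ga[j] + gb[j], ga[free], gb[free])
  }
  list(fn = fn, gr = gr, expand = expand, j = j, free = free)
}

#' Likelihood-ratio test of parameter equality across two conditions
#'
#' Tests whether one dual-retrieval parameter is equal in two conditions by
#' comparing the sum of the conditions' free fits to a joint fit in which the
#' named parameter is constrained equal (all other parameters free per
#' condition). `delta_g_squared = G2(joint constrained) - [G2(a) + G2(b)]` is
#' referred to chi-square(1).
#'
#' @param cond_a,cond_b Pattern counts for the two conditions (any form
#'   accepted by [drm_fit()]), or pre-computed `drm_fit` objects.
#' @param parameter One of `"D"`, `"F"`, `"J1"`, `"J2"`, `"J3"`, `"R"`.
#' @inheritParams drm_fit
#' @return A `drm_lr_test` object; [generics::tidy()] gives a one-row tibble
#'   with `parameter`, `delta_g_squared`, `df`, `p_value`.
#' @examples
#' a <- simulate_patterns(drm_params(0.4, 0.1, 0.5, 0.54, 0.6, 0.7), 320, seed = 1)
#' b <- simulate_patterns(drm_params(0.4, 0.1, 0.5, 0.34, 0.6, 0.7), 320, seed = 2)
#' tidy(drm_lr_test(a, b, "J1", n_starts = 5, seed = 3))
#' @export
drm_lr_test <- function(cond_a, cond_b, parameter, n_starts = 20, seed = 1) {
  if (!parameter %in% drm_param_names()) {
    stop("unknown model parameter `", parameter, "`; must be one of ",
         paste(drm_param_names(), collapse = ", "), call. = FALSE)
  }
  fit_a <- if (inherits(cond_a, "drm_fit")) cond_a else
    drm_fit(cond_a, n_starts = n_starts, seed = seed)
  fit_b <- if (inherits(cond_b, "drm_fit")) cond_b else
    drm_fit(cond_b, n_starts = n_starts, seed = seed + 1L)
  joint <- fit_joint_constrained(fit_a, fit_b, parameter,
                                 n_starts = n_starts, seed = seed + 2L)
  delta <- joint$g_squared - (fit_a$g_squared + fit_b$g_squared)
  if (delta < 0) {
    # the constrained fit beat a free fit: a free fit missed its optimum;
    # polish each free fit from the joint solution before judging
    fit_a <- polish_fit(fit_a, joint$estimates$a)
    fit_b <- polish_fit(fit_b, joint$estimates$b)
    delta <- joint$g_squared - (fit_a$g_squared + fit_b$g_squared)
  }
  if (delta < -1e-6) {
    stop("negative delta-G-squared (", format(delta),
         "): joint constrained fit did not converge; increase `n_starts`",
         call. = FALSE)
  }
  delta <- max(delta, 0)
  structure(list(
    parameter = parameter,
    delta_g_squared = delta,
    df = 1L,
    p_value = stats::pchisq(delta, df = 1, lower.tail = FALSE),
    free_fit_a = fit_a, free_fit_b = fit_b,
    constrained_fit_g_squared = joint$g_squared,
    constrained_estimates = joint$estimates
  ), class = "drm_lr_test")
}

# Re-optimize a free fit from an additional start; keep whichever optimum
# is better.
polish_fit <- function(fit, start) {
  obj <- make_nll(fit$observed)
  res <- tryCatch(
    stats::optim(pmin(pmax(start, 1e-6), 1 - 1e-6), obj$fn, obj$gr,
                 method = "L-BFGS-B", lower = 1e-6, upper = 1 - 1e-6,
                 control = list(factr = 1e5, maxit = 500)),
    error = function(e) NULL)
  if (is.null(res)) return(fit)
  pi_new <- model_pieces(res$par)$pi
  gsq_new <- g_squared(fit$observed, pi_new)
  if (gsq_new >= fit$g_squared) return(fit)
  fit$estimates <- structure(stats::setNames(res$par, drm_param_names()),
                             class = "drm_params")
  fit$g_squared <- gsq_new
  fit$p_value <- stats::pchisq(gsq_new, df = 1, lower.tail = FALSE)
  fit$log_likelihood <- -res$value + saturated_ll_const(fit$observed)
  fit$fitted_probs <- stats::setNames(pi_new, pattern_levels())
  fit$converged <- res$convergence == 0
  fit
}

fit_joint_constrained <- function(fit_a, fit_b, parameter, n_starts, seed) {
  ca <- fit_a$observed; cb <- fit_b$observed
  obj <- make_joint_nll(ca, cb, parameter)
  j <- obj$j; free <- obj$free
  ta <- as.numeric(fit_a$estimates[drm_param_names()])
  tb <- as.numeric(fit_b$estimates[drm_param_names()])
  # warm start at the free optima with the shared parameter averaged
  warm <- pmin(pmax(c((ta[j] + tb[j]) / 2, ta[free], tb[free]), 1e-6), 1 - 1e-6)
  starts <- rbind(warm, make_starts(n_starts, 11, seed))
  best <- multistart_optim(obj$fn, obj$gr, starts)
  pi_a <- model_pieces(obj$expand(best$par, 1))$pi
  pi_b <- model_pieces(obj$expand(best$par, 2))$pi
  list(g_squared = g_squared(ca, pi_a) + g_squared(cb, pi_b),
       estimates = list(a = obj$expand(best$par, 1), b = obj$expand(best$par, 2)))
}

#' @export
print.drm_lr_test <- function(x, ...) {
  cat(sprintf("<equality test>  %s: deltaG2(%d) = %.3f, p = %.4f\n",
              x$parameter, x$df, x$delta_g_squared, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.drm_lr_test <- function(x, ...) {
  tibble::tibble(parameter = x$parameter,
                 delta_g_squared = x$delta_g_squared,
                 df = x$df, p_value = x$p_value)
}

# ---- per-condition battery -------------------------------------------------

#' Fit all conditions and run the parameter-equality battery
#'
#' Fits the dual-retrieval model separately to every condition of a dataset
#' and, within each list organization, tests the equality of each of the six
#' parameters across the three pairs of judgment-of-learning conditions
#' (item vs none, list vs item, list vs none).
#'
#' @param data Either a trial-level tibble (as produced by
#'   [generate_experiment()] or the scoring pipeline, with columns
#'   `organization`, `jol_condition`, `recalled_t1`, `recalled_t2`,
#'   `recalled_t3`), or a long pattern-count tibble with columns `condition`,
#'   `pattern`, `count` (e.g. from [read_pattern_counts()]).
#' @inheritParams drm_fit
#' @param holm Also report Holm-adjusted p-values in the comparison table
#'   (the primary report is unadjusted, matching standard practice for these
#'   planned tests).
#' @return A `drm_battery` object with `$fits` (one row per condition: G2,
#'   p, then D, F, J1, J2, J3, R) and `$comparisons` (parameter, pair,
#'   delta_g_squared, df, p_value). `tidy()` returns `$fits`.
#' @export
fit_conditions <- function(data, n_starts = 20, seed = 1, holm = FALSE) {
  counts_by_cond <- condition_counts(data)
  if (length(counts_by_cond) == 0) stop("empty dataset", call. = FALSE)
  conds <- names(counts_by_cond)
  fits <- purrr::imap(counts_by_cond, function(cts, cond) {
    drm_fit(cts, n_starts = n_starts,
            seed = seed + match(cond, conds))
  })
  fit_rows <- purrr::imap(fits, function(f, cond) {
    dplyr::bind_cols(tibble::tibble(condition = cond),
                     tibble::as_tibble(as.list(unclass(f$estimates))),
                     glance(f)[, c("g_squared", "df", "p_value", "boundary")])
  }) |> purrr::list_rbind()
  comparisons <- battery_comparisons(fits, n_starts = n_starts, seed = seed)
  if (holm && nrow(comparisons) > 0) {
    comparisons <- dplyr::group_by(comparisons, .data$organization) |>
      dplyr::mutate(p_holm = stats::p.adjust(.data$p_value, "holm")) |>
      dplyr::ungroup()
  }
  structure(list(fits = fit_rows, comparisons = comparisons,
                 condition_fits = fits),
            class = "drm_battery")
}

# Aggregate input data into one 8-vector of pattern counts per condition.
condition_counts <- function(data) {
  stopifnot(is.data.frame(data))
  if (all(c("condition", "pattern", "count") %in% names(data))) {
    split(data[, c("pattern", "count")], data$condition) |>
      lapply(as_pattern_counts)
  } else if (all(c("recalled_t1", "recalled_t2", "recalled_t3") %in%
                 names(data))) {
    counts <- build_patterns(data)
    split(counts[, c("pattern", "count")], counts$condition) |>
      lapply(as_pattern_counts)
  } else {
    stop("`data` must be a trial-level table (recalled_t1..t3) or a long ",
         "pattern-count table (condition, pattern, count)", call. = FALSE)
  }
}

# The comparison battery run within each organization when condition labels
# look like "<organization>.<jol>"; otherwise all pairwise comparisons.
battery_comparisons <- function(fits, n_starts, seed) {
  conds <- names(fits)
  if (length(conds) < 2) {
    return(tibble::tibble(organization = character(), parameter = character(),
                          pair = character(), delta_g_squared = numeric(),
                          df = integer(), p_value = numeric()))
  }
  parts <- strsplit(conds, ".", fixed = TRUE)
  structured <- all(lengths(parts) == 2L)
  pairs <- if (structured) {
    org <- vapply(parts, `[`, "", 1)
    jol <- vapply(parts, `[`, "", 2)
    purrr::list_rbind(lapply(unique(org), function(o) {
      within <- conds[org == o]
      jw <- jol[org == o]
      want <- list(c("item", "none"), c("list", "item"), c("list", "none"))
      purrr::list_rbind(lapply(want, function(w) {
        if (all(w %in% jw)) {
          tibble::tibble(organization = o,
                         a = within[match(w[1], jw)],
                         b = within[match(w[2], jw)])
        } else NULL
      }))
    }))
  } else {
    cmb <- utils::combn(conds, 2)
    tibble::tibble(organization = NA_character_, a = cmb[1, ], b = cmb[2, ])
  }
  k <- 0L
  purrr::list_rbind(purrr::map(seq_len(nrow(pairs)), function(i) {
    purrr::list_rbind(purrr::map(drm_param_names(), function(p) {
      k <<- k + 1L
      lt <- drm_lr_test(fits[[pairs$a[i]]], fits[[pairs$b[i]]], p,
                        n_starts = n_starts, seed = seed + 100L + k)
      dplyr::bind_cols(
        tibble::tibble(organization = pairs$organization[i],
                       pair = paste(pairs$a[i], "vs", pairs$b[i])),
        tidy(lt))
    }))
  }))
}

#' @export
print.drm_battery <- function(x, digits = 3, ...) {
  cat("<dual-retrieval condition battery>\n\nPer-condition fits:\n")
  print(dplyr::mutate(x$fits, dplyr::across(dplyr::where(is.numeric),
                                            ~ round(.x, digits))))
  if (nrow(x$comparisons)) {
    cat("\nParameter-equality tests:\n")
    print(dplyr::mutate(x$comparisons,
                        dplyr::across(dplyr::where(is.numeric),
                                      ~ round(.x, digits))))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.drm_battery <- function(x, ...) x$fits
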