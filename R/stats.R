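#' One-way between-participants ANOVA
#'
#' Classical fixed-effects one-way ANOVA by sums of squares, reported with the
#' mean squared error and partial eta squared
#' (`SS_between / (SS_between + SS_within)`).
#'
#' @param data A data frame.
#' @param value,group Column names (strings or bare names) of the outcome and
#'   the grouping factor.
#' @return A one-row tibble: `f_statistic`, `df_between`, `df_within`, `mse`,
#'   `eta_p_squared`, `p_value`, plus `ss_between`, `ss_within`.
#' @examples
#' df <- data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'                  g = rep(c("a", "b", "c"), each = 3))
#' one_way_anova(df, y, g)
#' @export
one_way_anova <- function(data, value, group) {
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs at least 2 observations",
                              call. = FALSE)
  tab <- stats::anova(stats::lm(y ~ g))
  ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
  tibble::tibble(f_statistic = tab$`F value`[1],
                 df_between = tab$Df[1], df_within = tab$Df[2],
                 mse = tab$`Mean Sq`[2],
                 eta_p_squared = ssb / (ssb + ssw),
                 p_value = tab$`Pr(>F)`[1],
                 ss_between = ssb, ss_within = ssw)
}

#' Fisher's LSD pairwise comparisons
#'
#' Unadjusted pairwise t tests using the omnibus ANOVA's pooled error term:
#' `t = (M_a - M_b) / sqrt(MSE * (1/n_a + 1/n_b))` on the ANOVA's
#' within-groups degrees of freedom, with Cohen's
#' `d = (M_a - M_b) / sqrt(MSE)`. p-values are deliberately unadjusted (the
#' LSD convention).
#'
#' @inheritParams one_way_anova
#' @param anova Optional result of [one_way_anova()] on the same data; run
#'   internally when omitted.
#' @return A tibble, one row per ordered pair (a, b) with a before b in
#'   factor order: group means and SDs, `t_statistic`, `df`, `cohens_d`,
#'   `p_value`.
#' @export
pairwise_lsd <- function(data, value, group, anova = NULL) {
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  if (is.null(anova)) {
    anova <- one_way_anova(data, !!rlang::sym(value), !!rlang::sym(group))
  }
  y <- data[[value]]
  g <- factor(data[[group]])
  stats_by <- tibble::tibble(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(y, g, mean)),
    sd = as.numeric(tapply(y, g, stats::sd)))
  cmb <- utils::combn(levels(g), 2)
  purrr::list_rbind(purrr::map(seq_len(ncol(cmb)), function(i) {
    a <- stats_by[stats_by$group == cmb[1, i], ]
    b <- stats_by[stats_by$group == cmb[2, i], ]
    se <- sqrt(anova$mse * (1 / a$n + 1 / b$n))
    tval <- (a$mean - b$mean) / se
    tibble::tibble(group_a = a$group, group_b = b$group,
                   mean_a = a$mean, sd_a = a$sd, n_a = a$n,
                   mean_b = b$mean, sd_b = b$sd, n_b = b$n,
                   t_statistic = tval, df = anova$df_within,
                   cohens_d = (a$mean - b$mean) / sqrt(anova$mse),
                   p_value = 2 * stats::pt(abs(tval), anova$df_within,
                                           lower.tail = FALSE))
  }))
}

# One-tailed two-sample Student t (pooled variance), alternative a > b.
one_tailed_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  tibble::tibble(mean_a = mean(a), sd_a = stats::sd(a), n_a = na,
                 mean_b = mean(b), sd_b = stats::sd(b), n_b = nb,
                 t_statistic = tval, df = df,
                 cohens_d = (mean(a) - mean(b)) / sqrt(sp2),
                 p_value = stats::pt(tval, df, lower.tail = FALSE))
}

#' Run the full recall analysis pipeline
#'
#' Executes the package's complete analysis of a trial-level dataset
#' (synthetic or scored from transcripts): the median + 1.5 IQR outlier
#' screen; planned test-1 one-way ANOVAs comparing the three JOL conditions
#' within each list organization, with LSD pairwise tests; per-cell
#' dual-retrieval model fits with the full parameter-equality battery; and
#' the category-clustering follow-up (test-1 ARC, randomized lists, item-JOL
#' vs no-JOL, one-tailed pooled-variance t test).
#'
#' @param trials Trial-level tibble (see [generate_experiment()] /
#'   [score_transcripts()]); must contain `participant_id`, `organization`,
#'   `jol_condition`, `category`, the three recall flags and output
#'   positions.
#' @param n_starts,seed Passed to the model fits.
#' @return A `drm_report` list: `summaries` (post-screen participant
#'   summaries), `exclusions`, `anova` (per-organization test-1 ANOVA),
#'   `lsd` (pairwise tests), `battery` (model fits and equality tests),
#'   `arc_test` (clustering follow-up), and `arc_exclusions` (count of
#'   undefined ARC values dropped).
#' @export
run_recall_analysis <- function(trials, n_starts = 20, seed = 1) {
  need <- c("participant_id", "organization", "jol_condition", "category",
            paste0("recalled_t", 1:3), paste0("output_position_t", 1:3))
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!nrow(trials)) stop("trial table is empty", call. = FALSE)

  screened <- outlier_filter(participant_summaries(trials))
  keep_ids <- screened$participant_id[screened$included]
  trials_in <- trials[trials$participant_id %in% keep_ids, ]
  summ_in <- screened[screened$included, ]

  anovas <- purrr::list_rbind(purrr::map(unique(summ_in$organization),
    function(org) {
      df <- summ_in[summ_in$organization == org, ]
      dplyr::bind_cols(tibble::tibble(organization = org, test = 1L),
                       one_way_anova(df, recall_t1, jol_condition))
    }))
  lsd <- purrr::list_rbind(purrr::map(unique(summ_in$organization),
    function(org) {
      df <- summ_in[summ_in$organization == org, ]
      an <- one_way_anova(df, recall_t1, jol_condition)
      dplyr::bind_cols(tibble::tibble(organization = org, test = 1L),
                       pairwise_lsd(df, recall_t1, jol_condition, anova = an))
    }))

  battery <- fit_conditions(trials_in, n_starts = n_starts, seed = seed)

  arcs <- arc_by_participant(trials_in, tests = 1)
  arcs_rand <- arcs[arcs$organization == "randomized", ]
  a <- arcs_rand$arc[arcs_rand$jol_condition == "item" & arcs_rand$defined]
  b <- arcs_rand$arc[arcs_rand$jol_condition == "none" & arcs_rand$defined]
  arc_test <- if (length(a) >= 2 && length(b) >= 2) one_tailed_t(a, b) else NULL
  n_undef <- sum(!arcs_rand$defined[arcs_rand$jol_condition %in%
                                      c("item", "none")])

  structure(list(summaries = summ_in,
                 exclusions = attr(screened, "exclusions"),
                 anova = anovas, lsd = lsd, battery = battery,
                 arc = arcs, arc_test = arc_test,
                 arc_exclusions = n_undef,
                 seed = seed),
            class = "drm_report")
}

#' @export
print.drm_report <- function(x, digits = 3, ...) {
  cat("== Recall analysis report ==\n\n")
  cat(nrow(x$exclusions), "participant(s) excluded by the median + 1.5 IQR",
      "screen\n\nTest-1 one-way ANOVAs (JOL condition within organization):\n")
  print(dplyr::mutate(x$anova[, c("organization", "f_statistic", "df_between",
                                  "df_within", "mse", "eta_p_squared",
                                  "p_value")],
                      dplyr::across(dplyr::where(is.numeric),
                                    ~ round(.x, digits))))
  cat("\nLSD pairwise tests:\n")
  print(dplyr::mutate(x$lsd[, c("organization", "group_a", "group_b",
                                "t_statistic", "df", "cohens_d", "p_value")],
                      dplyr::across(dplyr::where(is.numeric),
                                    ~ round(.x, digits))))
  cat("\n")
  print(x$battery, digits = digits)
  if (!is.null(x$arc_test)) {
    cat(sprintf(paste0("\nARC follow-up (test 1, randomized, item vs none, ",
                       "one-tailed): t(%d) = %.2f, d = %.2f, p = %.3f\n"),
                x$arc_test$df, x$arc_test$t_statistic, x$arc_test$cohens_d,
                x$arc_test$p_value))
    cat(x$arc_exclusions, "undefined ARC value(s) excluded\n")
  }
  invisible(x)
}
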