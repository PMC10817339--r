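#' Plot observed vs fitted pattern frequencies
#'
#' @param object A [drm_fit()] object.
#' @param ... Unused.
#' @return A ggplot comparing observed pattern proportions to the fitted
#'   model probabilities.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.drm_fit <- function(object, ...) {
  df <- tibble::tibble(
    pattern = factor(pattern_levels(), levels = pattern_levels()),
    observed = as.numeric(object$observed) / object$n_items,
    fitted = as.numeric(object$fitted_probs)) |>
    tidyr::pivot_longer(c("observed", "fitted"), names_to = "source",
                        values_to = "proportion")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$proportion,
                                   fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "three-test recall pattern", y = "proportion",
                  fill = NULL,
                  title = sprintf("Dual-retrieval fit: G2(%d) = %.2f",
                                  object$df, object$g_squared)) +
    ggplot2::theme_minimal()
}

#' Plot per-condition parameter estimates
#'
#' @param object A `drm_battery` from [fit_conditions()].
#' @param ... Unused.
#' @return A ggplot of the six parameter estimates by condition.
#' @exportS3Method ggplot2::autoplot
autoplot.drm_battery <- function(object, ...) {
  df <- tidyr::pivot_longer(object$fits,
                            cols = dplyr::all_of(drm_param_names()),
                            names_to = "parameter", values_to = "estimate") |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = drm_param_names()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$estimate,
                                   fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "ML estimate", fill = "condition") +
    ggplot2::theme_minimal()
}

#' Plot recall proportions by cell and test
#'
#' @param trials A trial-level tibble.
#' @return A ggplot of mean recall per test, faceted by organization.
#' @export
plot_recall <- function(trials) {
  df <- participant_summaries(trials) |>
    tidyr::pivot_longer(dplyr::starts_with("recall_t"), names_to = "test",
                        values_to = "recall", names_prefix = "recall_t")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test, y = .data$recall,
                                   colour = .data$jol_condition)) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2,
                          position = ggplot2::position_dodge(0.3)) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar",
                          width = 0.2,
                          position = ggplot2::position_dodge(0.3)) +
    ggplot2::facet_wrap(~organization) +
    ggplot2::labs(x = "recall test", y = "proportion recalled",
                  colour = "JOL condition") +
    ggplot2::theme_minimal()
}
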