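#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot MEC performance curves
#'
#' Reliability P{c-MEC} against the bi-substitution probability, one line
#' per coverage model (and per length, when the table mixes lengths), with
#' a log-scaled error axis.
#'
#' @param object a `performance_curve` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot performance_curve
#' @export
autoplot.performance_curve <- function(object, ...) {
  lab <- if (length(unique(object$l)) > 1L)
    paste0(object$model, ", l=", format(object$l, scientific = TRUE,
                                        digits = 2))
  else object$model
  df <- dplyr::mutate(object, curve = lab)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_e, y = .data$p_cmec,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "bi-substitution probability p_e",
                  y = "P{c-MEC}", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a high bi-substitution census sweep
#'
#' @param census the `census` tibble from [run_bisub_experiment()].
#' @return a ggplot of flagged-site counts against coverage, per profile.
#' @export
plot_bisub_census <- function(census) {
  ggplot2::ggplot(census,
                  ggplot2::aes(x = .data$coverage, y = .data$high_bisub_count,
                               colour = .data$profile)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "mean total coverage",
                  y = "SNPs with bi-substitution rate >= threshold",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot assembly accuracy and continuity against coverage
#'
#' @param summary the `summary` tibble from [run_assembly_experiment()].
#' @return a ggplot with switch error rate and mean block length panels.
#' @export
plot_assembly_metrics <- function(summary) {
  long <- tidyr::pivot_longer(
    summary,
    cols = c("switch_error_rate_mean", "avg_block_length_mean"),
    names_to = "metric", values_to = "mean")
  long$sd <- ifelse(long$metric == "switch_error_rate_mean",
                    summary$switch_error_rate_sd[match(long$coverage,
                                                       summary$coverage)],
                    summary$avg_block_length_sd[match(long$coverage,
                                                      summary$coverage)])
  long$metric <- ifelse(long$metric == "switch_error_rate_mean",
                        "switch error rate", "average block length (SNPs)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$coverage, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "mean total coverage", y = NULL) +
    ggplot2::theme_minimal()
}
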