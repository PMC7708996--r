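#' Plot cumulative payoffs by agent type
#'
#' Boxplots of per-agent cumulative payoff grouped by type, the package's
#' standard view of comparative social performance.
#'
#' @param object A [run_simulation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mood_sim <- function(object, ...) {
  ggplot2::ggplot(
    object$agents,
    ggplot2::aes(x = .data$type, y = .data$cumulative_payoff,
                 fill = .data$type)
  ) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "Cumulative payoff",
      title = sprintf("Payoffs after %d rounds", object$config$n_rounds)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sweep result
#'
#' Mean payoff (replicate means, with a point per seed) against the swept
#' parameter, one line per agent type. Numeric grids with wide dynamic range
#' are drawn on a log axis.
#'
#' @param sweep_result Output of [run_sweep()].
#' @param log_x Use a log10 x axis (default: automatic).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep_result, log_x = NULL) {
  num <- is.numeric(sweep_result$setting)
  if (is.null(log_x)) {
    log_x <- num && min(sweep_result$setting) > 0 &&
      max(sweep_result$setting) / min(sweep_result$setting) > 100
  }
  agg <- sweep_result |>
    dplyr::group_by(.data$setting, .data$type) |>
    dplyr::summarise(mean_payoff = mean(.data$mean_payoff), .groups = "drop")
  p <- ggplot2::ggplot(
    agg, ggplot2::aes(x = .data$setting, y = .data$mean_payoff,
                      colour = .data$type, group = .data$type)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = unique(sweep_result$sweep), y = "Mean payoff") +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}
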