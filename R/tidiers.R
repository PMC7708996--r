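#' Tidy a simulation into one row per agent
#'
#' @param x A [run_simulation()] result.
#' @param ... Unused.
#' @return A tibble with the per-agent traits and outcomes.
#' @export
tidy.mood_sim <- function(x, ...) {
  cols <- intersect(
    c("id", "type", "beta0", "kappa", "mood0", "lambda", "omega_mean",
      "drive", "target_degree", "realized_degree", "cumulative_payoff",
      "n_interactions", "n_active_rounds", "mood", "beta_t", "traces_alive"),
    names(x$agents)
  )
  x$agents[, cols]
}

#' One-row summary of a simulation
#'
#' @param x A [run_simulation()] result.
#' @param ... Unused.
#' @return A one-row tibble: run size, interaction totals, payoff totals,
#'   and per-type mean payoffs in wide form.
#' @export
glance.mood_sim <- function(x, ...) {
  s <- summarize_types(x)
  wide <- tidyr::pivot_wider(
    s[, c("type", "mean_payoff")],
    names_from = "type", values_from = "mean_payoff",
    names_prefix = "mean_payoff_"
  )
  dplyr::bind_cols(
    tibble::tibble(
      n_agents = nrow(x$agents),
      n_rounds = x$config$n_rounds,
      n_interactions = if (is.null(x$events)) 0L else nrow(x$events),
      total_payoff = sum(x$agents$cumulative_payoff),
      seed = x$seed
    ),
    wide
  )
}
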