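#' Per-type payoff summary of one simulation
#'
#' Mean and SD of cumulative payoff, interaction count, activity rate, and
#' realized degree by agent type.
#'
#' @param sim A [run_simulation()] result.
#' @return A tibble, one row per agent type.
#' @export
summarize_types <- function(sim) {
  sim$agents |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_payoff = mean(.data$cumulative_payoff),
      sd_payoff = stats::sd(.data$cumulative_payoff),
      mean_interactions = mean(.data$n_interactions),
      activity_rate = mean(.data$n_active_rounds) / sim$config$n_rounds,
      mean_degree = mean(.data$realized_degree),
      .groups = "drop"
    )
}

#' Percentage payoff difference versus the rational baseline
#'
#' Expresses each type's mean cumulative payoff as a signed percentage
#' difference from the rational-type mean computed on the same runs.
#'
#' @param type_summary A tibble with `type` and `mean_payoff` columns (from
#'   [summarize_types()] or replicate means).
#' @return The input with a `pct_vs_rational` column.
#' @export
payoff_vs_rational <- function(type_summary) {
  base <- type_summary$mean_payoff[type_summary$type == "rational"]
  if (length(base) != 1) {
    stop("exactly one rational row is required as the baseline", call. = FALSE)
  }
  dplyr::mutate(
    type_summary,
    pct_vs_rational = ifelse(.data$type == "rational", 0,
                             100 * (.data$mean_payoff - base) / base)
  )
}

#' Run seeded replicate simulations
#'
#' Runs the same configuration under several seeds and stacks the per-type
#' summaries.
#'
#' @param config A [default_config()] object.
#' @param seeds Integer vector of seeds, one replicate per seed.
#' @return A long tibble of per-type summaries with a `seed` column.
#' @export
run_replicates <- function(config = default_config(), seeds = 1:10) {
  purrr::map(seeds, function(s) {
    dplyr::mutate(summarize_types(run_simulation(config, seed = s)), seed = s)
  }) |>
    purrr::list_rbind()
}

#' Pool replicate summaries into per-type means
#'
#' @param replicates Output of [run_replicates()].
#' @return A tibble with one row per type and the replicate-mean payoff.
#' @export
pool_replicates <- function(replicates) {
  replicates |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(sd_across_seeds = stats::sd(.data$mean_payoff),
                     mean_payoff = mean(.data$mean_payoff),
                     .groups = "drop") |>
    dplyr::relocate("sd_across_seeds", .after = "mean_payoff")
}

#' Specify a parameter sweep
#'
#' Describes one of the comparative experiments: which parameter is varied,
#' over which grid, with how many seeded replicates per grid point, on top of
#' which base configuration. Supported names:
#' \describe{
#'   \item{type_comparison}{no parameter varied; the default society.}
#'   \item{composition}{representation of a focal type, remainder split
#'     equally (grid: fractions; needs `focal_type`).}
#'   \item{diversity}{depressed connection diversity pi.}
#'   \item{forgetting}{forgetting rate theta, all agents.}
#'   \item{bias}{encoding bias arms `"positive"` / `"negative"` for all
#'     agents (gradient ratio 2 and 1/2).}
#'   \item{mood_dependence}{retrieval selectivity gamma, all agents.}
#'   \item{sensitivity}{trait reward sensitivity of a focal type fixed at
#'     each grid value (needs `focal_type`).}
#' }
#'
#' @param name Sweep name (see above).
#' @param grid Vector of parameter settings; defaults per experiment.
#' @param n_replicates Seeded replicates per grid point.
#' @param base_config Configuration used for everything not swept.
#' @param focal_type Agent type for composition/sensitivity sweeps.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(name = c("type_comparison", "composition", "diversity",
                                "forgetting", "bias", "mood_dependence",
                                "sensitivity"),
                       grid = NULL, n_replicates = 10,
                       base_config = default_config(), focal_type = NULL) {
  name <- match.arg(name)
  if (is.null(grid)) {
    grid <- switch(name,
      type_comparison = NA,
      composition = c(0.10, 0.25, 0.40, 0.625),
      diversity = c(0.2, 0.3, 0.4, 0.5),
      forgetting = c(1e-4, 1e-3, 1e-2, 1e-1, 1, 10),
      bias = c("positive", "negative"),
      mood_dependence = c(1e-2, 1e-1, 1, 10, 100),
      sensitivity = if (identical(focal_type, "depressed")) {
        seq(0.1, 0.9, by = 0.2)
      } else {
        c(2, 4, 6, 8, 10)
      }
    )
  }
  if (name %in% c("composition", "sensitivity") && is.null(focal_type)) {
    stop(sprintf("`focal_type` is required for the %s sweep", name), call. = FALSE)
  }
  structure(
    list(name = name, grid = grid, n_replicates = n_replicates,
         base_config = base_config, focal_type = focal_type),
    class = "sweep_spec"
  )
}

apply_setting <- function(config, name, value, focal_type) {
  switch(name,
    type_comparison = config,
    diversity = {
      config$depressed_diversity <- value
      config
    },
    forgetting = {
      m <- config$memory
      config$memory <- memory_params(
        forget_rate = value, min_strength = m$min_strength,
        grad_neg = m$grad_neg, grad_pos = m$grad_pos,
        intercept = m$intercept, mood_dependence = m$mood_dependence
      )
      config$memory_by_type <- list()
      config
    },
    mood_dependence = {
      m <- config$memory
      config$memory <- memory_params(
        forget_rate = m$forget_rate, min_strength = m$min_strength,
        grad_neg = m$grad_neg, grad_pos = m$grad_pos,
        intercept = m$intercept, mood_dependence = value
      )
      config$memory_by_type <- list()
      config
    },
    bias = {
      m <- config$memory
      gr <- if (value == "positive") c(neg = m$grad_neg / 2, pos = m$grad_pos)
            else c(neg = m$grad_neg, pos = m$grad_pos / 2)
      config$memory <- memory_params(
        forget_rate = m$forget_rate, min_strength = m$min_strength,
        grad_neg = gr[["neg"]], grad_pos = gr[["pos"]],
        intercept = m$intercept, mood_dependence = m$mood_dependence
      )
      config$memory_by_type <- list()
      config
    },
    composition = {
      others <- setdiff(names(config$proportions), focal_type)
      p <- stats::setNames(rep((1 - value) / length(others),
                               length(config$proportions)),
                           names(config$proportions))
      p[focal_type] <- value
      config$proportions <- p
      config
    },
    sensitivity = {
      config$fixed_beta0 <- stats::setNames(value, focal_type)
      config
    }
  )
}

#' Run a parameter sweep
#'
#' Runs `n_replicates` seeded simulations at every grid point, holding all
#' non-swept parameters at the base configuration, and returns the long
#' per-type payoff table. Replicate seeds are derived deterministically from
#' `seed` and shared across grid points (paired comparisons). Infeasible
#' grid points (for example a diversity value the type mix cannot supply)
#' are skipped with a warning.
#'
#' @param spec A [sweep_spec()] object.
#' @param seed Master seed.
#' @return A tibble: one row per (setting, seed, type) with summary columns.
#' @export
run_sweep <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sweep_spec"))
  seeds <- seed + seq_len(spec$n_replicates) - 1L
  out <- list()
  for (g in seq_along(spec$grid)) {
    value <- spec$grid[g]
    cfg <- tryCatch(
      apply_setting(spec$base_config, spec$name, value, spec$focal_type),
      error = function(e) e
    )
    if (inherits(cfg, "error")) {
      warning(sprintf("skipping infeasible setting %s: %s", value,
                      conditionMessage(cfg)), call. = FALSE)
      next
    }
    res <- purrr::map(seeds, function(s) {
      sim <- tryCatch(run_simulation(cfg, seed = s), error = function(e) e)
      if (inherits(sim, "error")) return(NULL)
      dplyr::mutate(summarize_types(sim), seed = s)
    }) |> purrr::list_rbind()
    if (is.null(res) || nrow(res) == 0) {
      warning(sprintf("skipping infeasible setting %s", value), call. = FALSE)
      next
    }
    out[[length(out) + 1]] <- dplyr::mutate(
      res, sweep = spec$name, setting = value, .before = 1
    )
  }
  purrr::list_rbind(out)
}

#' Emotional-bias experiment
#'
#' Runs two arms of the default society with every agent positively biased
#' (encoding gradient ratio 2) versus negatively biased (ratio 1/2), and
#' expresses each arm's per-type mean payoff as a percentage difference from
#' the pooled two-arm mean of that type (the per-type baseline, 0 by
#' construction).
#'
#' @param base_config Base configuration.
#' @param n_replicates Seeded replicates per arm.
#' @param seed Master seed.
#' @return A tibble with columns `type`, `bias`, `mean_payoff`,
#'   `pct_vs_baseline`.
#' @export
bias_experiment <- function(base_config = default_config(),
                            n_replicates = 10, seed = 1L) {
  spec <- sweep_spec("bias", n_replicates = n_replicates,
                     base_config = base_config)
  run_sweep(spec, seed = seed) |>
    dplyr::group_by(.data$type, bias = .data$setting) |>
    dplyr::summarise(mean_payoff = mean(.data$mean_payoff), .groups = "drop") |>
    dplyr::group_by(.data$type) |>
    dplyr::mutate(
      pct_vs_baseline = 100 * (.data$mean_payoff - mean(.data$mean_payoff)) /
        mean(.data$mean_payoff)
    ) |>
    dplyr::ungroup()
}

#' Recompute per-type metrics from an event log
#'
#' Reconstructs per-agent cumulative payoffs and interaction counts from the
#' interaction log alone and summarises them by type — the conservation
#' cross-check against the online per-agent accumulators.
#'
#' @param events An interaction-log tibble.
#' @param agents The per-agent tibble of the same run.
#' @return A tibble of per-type means recomputed from the log.
#' @export
summarize_events <- function(events, agents) {
  if (is.null(events) || nrow(events) == 0) {
    stop("empty event log", call. = FALSE)
  }
  long <- dplyr::bind_rows(
    tibble::tibble(id = events$id_a, payoff = events$payoff_a),
    tibble::tibble(id = events$id_b, payoff = events$payoff_b)
  )
  per_agent <- long |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(cumulative_payoff = sum(.data$payoff),
                     n_interactions = dplyr::n(), .groups = "drop")
  agents |>
    dplyr::select("id", "type") |>
    dplyr::left_join(per_agent, by = "id") |>
    tidyr::replace_na(list(cumulative_payoff = 0, n_interactions = 0)) |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(mean_payoff = mean(.data$cumulative_payoff),
                     mean_interactions = mean(.data$n_interactions),
                     .groups = "drop")
}
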