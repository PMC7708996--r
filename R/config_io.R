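#' Read a simulation configuration from YAML
#'
#' Top-level keys mirror the arguments of [default_config()]; `payoff:` and
#' `memory:` blocks map onto [payoff_constants()] and [memory_params()].
#' Missing keys take the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[setdiff(names(raw), c("payoff", "memory", "proportions"))]
  if (!is.null(raw$payoff)) args$payoff <- do.call(payoff_constants, raw$payoff)
  if (!is.null(raw$memory)) args$memory <- do.call(memory_params, raw$memory)
  if (!is.null(raw$proportions)) args$proportions <- unlist(raw$proportions)
  do.call(default_config, args)
}

#' Write a resolved configuration to YAML
#'
#' Echoes the fully resolved configuration (all defaults filled in) so a run
#' directory records its provenance.
#'
#' @param config A `sim_config` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  out <- list(
    n_agents = config$n_agents,
    proportions = as.list(config$proportions),
    n_rounds = config$n_rounds,
    payoff = unclass(config$payoff),
    beta_max = config$beta_max,
    kappa_mood = config$kappa_mood,
    memory = unclass(config$memory),
    depressed_diversity = config$depressed_diversity,
    omega_mean_range = config$omega_mean_range,
    omega_resample_every = config$omega_resample_every,
    cold_start = config$cold_start,
    broadcast = config$broadcast
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
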