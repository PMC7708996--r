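#' Simulation configuration
#'
#' Assembles every constant of a run: society size and type mix, round count,
#' payoff constants, trait ranges, memory parameters (with optional per-type
#' overrides, used by the emotional-bias experiment), the depressed-agent
#' connection diversity, the bipolar rhythm settings, and the cold-start
#' expectation rule.
#'
#' @param n_agents Number of agents.
#' @param proportions Named fractions (rational, manic, depressed, bipolar)
#'   summing to 1.
#' @param n_rounds Number of interaction rounds.
#' @param payoff A [payoff_constants()] object.
#' @param beta_max Maximum reward sensitivity (10 in all experiments).
#' @param kappa_mood Rate of mood change for manic and depressed agents
#'   (rational agents use 0; bipolar agents do not use the mood update).
#' @param memory A [memory_params()] object used by every agent.
#' @param memory_by_type Optional named list of [memory_params()] overriding
#'   `memory` for specific types, e.g.
#'   `list(depressed = memory_params(grad_pos = 40))`.
#' @param depressed_diversity Fraction pi of a depressed agent's neighbours
#'   that are themselves depressed; the rest is split equally across the
#'   other three types. Must not exceed what the type mix can supply.
#' @param omega_mean_range Range of the per-agent mean angular rate of the
#'   bipolar rhythm (radians/round), sampled uniformly per agent.
#' @param omega_resample_every Rounds between resampling of the bipolar
#'   angular rate.
#' @param cold_start Expectation used when memory retrieval comes back empty:
#'   `"uniform"` (a fresh Uniform(0,1) draw per occasion, the default) or a
#'   fixed level in \[0, 1\].
#' @param broadcast Whether interaction gists are broadcast to neighbours.
#' @param drive_override Optional fixed participation probability applied to
#'   every agent (testing hook); `NULL` uses the trait-derived drive.
#' @return A list of class `sim_config`.
#' @export
default_config <- function(n_agents = 200,
                           proportions = c(rational = 0.25, manic = 0.25,
                                           depressed = 0.25, bipolar = 0.25),
                           n_rounds = 2000,
                           payoff = payoff_constants(),
                           beta_max = 10,
                           kappa_mood = 0.1,
                           memory = memory_params(),
                           memory_by_type = list(),
                           depressed_diversity = 0.25,
                           omega_mean_range = c(0.01, 0.5),
                           omega_resample_every = 50,
                           cold_start = "uniform",
                           broadcast = TRUE,
                           drive_override = NULL) {
  types <- c("rational", "manic", "depressed", "bipolar")
  if (!all(names(proportions) %in% types) || is.null(names(proportions))) {
    stop("`proportions` must be named with agent types", call. = FALSE)
  }
  proportions <- proportions[intersect(types, names(proportions))]
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("`proportions` must sum to 1", call. = FALSE)
  }
  stopifnot(
    n_agents >= 2, n_rounds >= 1, beta_max > 1,
    kappa_mood >= 0, kappa_mood <= 1,
    depressed_diversity >= 0, depressed_diversity <= 1,
    inherits(payoff, "payoff_constants"), inherits(memory, "memory_params"),
    omega_resample_every >= 1, length(omega_mean_range) == 2,
    all(omega_mean_range > 0)
  )
  if (!identical(cold_start, "uniform")) check_range(cold_start, 0, 1, "cold_start")
  if (length(memory_by_type) > 0) {
    stopifnot(all(names(memory_by_type) %in% types),
              all(vapply(memory_by_type, inherits, TRUE, "memory_params")))
  }
  structure(
    list(
      n_agents = as.integer(n_agents), proportions = proportions,
      n_rounds = as.integer(n_rounds), payoff = payoff, beta_max = beta_max,
      kappa_mood = kappa_mood, memory = memory,
      memory_by_type = memory_by_type,
      depressed_diversity = depressed_diversity,
      omega_mean_range = omega_mean_range,
      omega_resample_every = as.integer(omega_resample_every),
      cold_start = cold_start, broadcast = broadcast,
      drive_override = drive_override
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d agents (%s), %d rounds\n", x$n_agents,
              paste(sprintf("%s %.0f%%", names(x$proportions),
                            100 * x$proportions), collapse = ", "),
              x$n_rounds))
  cat(sprintf("  beta_max %g, kappa %g, pi %g, cold start %s, broadcast %s\n",
              x$beta_max, x$kappa_mood, x$depressed_diversity,
              paste(x$cold_start, collapse = ""), x$broadcast))
  print(x$payoff)
  print(x$memory)
  invisible(x)
}

#' Participation drive implied by trait reward sensitivity
#'
#' Min-max rescaling of beta0 onto the drive scale: rational agents
#' participate with probability 0.5 each round, depressed agents below 0.5
#' (`0.5 * beta0`), manic agents above
#' (`0.5 + 0.5 * (beta0 - 1) / (beta_max - 1)`).
#'
#' @inheritParams initial_mood
#' @return Participation probability in \[0, 1\]. Vectorised over `beta0`.
#' @export
drive_of <- function(beta0, beta_max = 10) {
  stopifnot(length(beta_max) == 1, beta_max > 1)
  if (any(beta0 < 0 | beta0 > beta_max)) {
    stop("`beta0` must lie in [0, beta_max]", call. = FALSE)
  }
  ifelse(beta0 < 1, 0.5 * beta0,
    ifelse(beta0 > 1, 0.5 + 0.5 * (beta0 - 1) / (beta_max - 1), 0.5)
  )
}

#' Target neighbourhood size implied by trait reward sensitivity
#'
#' Social reach scales with reward sensitivity exactly like drive, but on the
#' scale of the society: half the society for rational agents, less for
#' depressed, more for manic. Values are rounded to the nearest integer and
#' capped at `n_agents - 1` (a node cannot have more neighbours than that;
#' the cap closes the formula's open endpoint at `beta0 = beta_max`).
#'
#' @inheritParams initial_mood
#' @param n_agents Society size (>= 2).
#' @return Integer target degree. Vectorised over `beta0`.
#' @export
degree_of <- function(beta0, beta_max = 10, n_agents) {
  stopifnot(n_agents >= 2)
  raw <- drive_of(beta0, beta_max) * n_agents
  pmin(as.integer(round(raw)), n_agents - 1L)
}

type_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

#' Spawn the heterogeneous agent population
#'
#' Creates one agent per row with its type, trait reward sensitivity sampled
#' uniformly from the type's permitted range (rational: exactly 1; manic:
#' (1, beta_max\]; depressed: \[0, 1)), the mood-change rate, the initial
#' mood implied by the trait ([initial_mood()], or the rhythm offset for
#' bipolar agents), the bipolar rhythm traits, the participation drive, the
#' target degree, and the per-agent memory parameters (after any per-type
#' override).
#'
#' Bipolar agents do not carry a sampled trait sensitivity: their offset
#' lambda ~ Uniform(-1, 1) fixes the initial mood, and beta0 is derived from
#' it through [bipolar_reward_sensitivity()], so drive and degree remain
#' constant traits.
#'
#' Uses the current RNG state; wrap in [withr::with_seed()] for
#' reproducibility.
#'
#' @param config A [default_config()] object.
#' @return A tibble with one row per agent.
#' @export
spawn_population <- function(config = default_config()) {
  counts <- type_counts(config$n_agents, config$proportions)
  type <- rep(names(counts), counts)
  n <- length(type)
  bmax <- config$beta_max

  beta0 <- numeric(n)
  mood0 <- numeric(n)
  kappa <- numeric(n)
  lambda <- rep(NA_real_, n)
  omega_mean <- rep(NA_real_, n)

  for (ty in unique(type)) {
    i <- which(type == ty)
    if (ty == "rational") {
      beta0[i] <- 1
      kappa[i] <- 0
    } else if (ty == "manic") {
      beta0[i] <- stats::runif(length(i), 1, bmax)
      kappa[i] <- config$kappa_mood
    } else if (ty == "depressed") {
      beta0[i] <- stats::runif(length(i), 0, 1)
      kappa[i] <- config$kappa_mood
    } else { # bipolar
      lambda[i] <- stats::runif(length(i), -1, 1)
      omega_mean[i] <- stats::runif(length(i), config$omega_mean_range[1],
                                    config$omega_mean_range[2])
      mood0[i] <- bipolar_mood(0, 1, lambda[i])
      beta0[i] <- bipolar_reward_sensitivity(mood0[i], bmax)
      kappa[i] <- NA_real_
    }
  }
  # sensitivity sweeps pin the trait of one (manic or depressed) type
  if (!is.null(config$fixed_beta0)) {
    ty <- names(config$fixed_beta0)
    stopifnot(ty %in% c("manic", "depressed"))
    beta0[type == ty] <- unname(config$fixed_beta0)
  }
  nb <- type != "bipolar"
  mood0[nb] <- initial_mood(beta0[nb], bmax)

  mem <- config$memory
  field <- function(name) {
    v <- rep(mem[[name]], n)
    for (ty in names(config$memory_by_type)) {
      v[type == ty] <- config$memory_by_type[[ty]][[name]]
    }
    v
  }

  drive <- drive_of(beta0, bmax)
  if (!is.null(config$drive_override)) {
    drive <- rep(config$drive_override, n)
  }

  tibble::tibble(
    id = seq_len(n),
    type = type,
    beta0 = beta0,
    kappa = kappa,
    mood0 = mood0,
    lambda = lambda,
    omega_mean = omega_mean,
    drive = drive,
    target_degree = degree_of(beta0, bmax, n),
    forget_rate = field("forget_rate"),
    min_strength = field("min_strength"),
    grad_neg = field("grad_neg"),
    grad_pos = field("grad_pos"),
    intercept = field("intercept"),
    mood_dependence = field("mood_dependence")
  )
}
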