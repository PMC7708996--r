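#' Sample the active agents for one round
#'
#' Each agent independently participates with probability equal to its drive.
#' Uses the current RNG state.
#'
#' @param agents Population tibble with a `drive` column.
#' @return Integer vector of active agent ids.
#' @export
sample_active <- function(agents) {
  agents$id[stats::runif(nrow(agents)) < agents$drive]
}

#' Pair the active agents on the network
#'
#' Builds a matching on the subgraph induced by the active agents: active
#' agents are visited in random order and each still-unmatched agent picks a
#' uniformly random unmatched active neighbour. Agents with no available
#' partner stay unmatched for the round.
#'
#' @param network A [build_network()] result.
#' @param active Integer vector of active agent ids.
#' @return A tibble with columns `id_a`, `id_b`, one row per pair.
#' @export
pair_active <- function(network, active) {
  is_active <- logical(nrow(network$agents))
  is_active[active] <- TRUE
  matched <- logical(nrow(network$agents))
  ord <- if (length(active) > 1) sample(active) else active
  id_a <- integer(0)
  id_b <- integer(0)
  for (a in ord) {
    if (matched[a]) next
    cand <- network$adjacency[[a]]
    cand <- cand[is_active[cand] & !matched[cand]]
    if (length(cand) == 0) next
    b <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
    matched[a] <- matched[b] <- TRUE
    id_a <- c(id_a, a)
    id_b <- c(id_b, b)
  }
  tibble::tibble(id_a = id_a, id_b = id_b)
}

#' Gist traces produced by broadcasting one interaction
#'
#' After an interaction, each participant's neighbours (other than the
#' counterpart) receive a secondhand trace about the counterpart: its
#' cooperation level with neutral emotion, encoded at the receiver's
#' intercept strength — reputationally useful but emotionally flat and
#' weakly encoded.
#'
#' @param record One interaction record (a one-row tibble or list with
#'   `id_a`, `id_b`, `c_a`, `c_b`).
#' @param network A [build_network()] result.
#' @param t Round of the interaction.
#' @return A tibble of gist traces with an `owner_id` column; `nrow()` is the
#'   number of gists written.
#' @export
broadcast_gists <- function(record, network, t) {
  agents <- network$agents
  rec_a <- setdiff(network$adjacency[[record$id_a]], record$id_b)
  rec_b <- setdiff(network$adjacency[[record$id_b]], record$id_a)
  tibble::tibble(
    owner_id = c(rec_a, rec_b),
    counterpart_id = c(rep(record$id_b, length(rec_a)),
                       rep(record$id_a, length(rec_b))),
    cooperation = c(rep(record$c_b, length(rec_a)),
                    rep(record$c_a, length(rec_b))),
    emotion = 0,
    initial_strength = agents$intercept[c(rec_a, rec_b)],
    encoded_at = as.integer(t),
    firsthand = FALSE
  )
}

agent_params <- function(agents, i) {
  memory_params(
    forget_rate = agents$forget_rate[i], min_strength = agents$min_strength[i],
    grad_neg = agents$grad_neg[i], grad_pos = agents$grad_pos[i],
    intercept = agents$intercept[i], mood_dependence = agents$mood_dependence[i]
  )
}

#' Execute one interaction between two paired agents
#'
#' In order: both agents purge and retrieve their traces about each other
#' (refreshing hits), form expectations from the retrieved cooperation
#' levels (cold start when empty), cooperate at their expectations
#' (simultaneously, from pre-round state), collect the bilinear CPD payoffs,
#' appraise emotions with their current reward sensitivities, encode
#' firsthand traces about each other, and (non-bipolar) update mood.
#'
#' This is the reference implementation used by `run_simulation(engine =
#' "reference")`; the compiled engine performs the same steps.
#'
#' @param state Simulation state list with `agents` (tibble including `mood`,
#'   `beta_t`, `cumulative_payoff`), `memory` (list of per-agent trace
#'   tibbles), and `config`.
#' @param a,b Agent ids (must be network neighbours).
#' @param t Round index.
#' @return The updated state; the interaction record is in `state$last_record`.
#' @export
run_interaction <- function(state, a, b, t) {
  cfg <- state$config
  ag <- state$agents
  pa <- agent_params(ag, a)
  pb <- agent_params(ag, b)

  ra <- retrieve_traces(purge_traces(state$memory[[a]], t, pa), b,
                        ag$mood[a], t, pa)
  rb <- retrieve_traces(purge_traces(state$memory[[b]], t, pb), a,
                        ag$mood[b], t, pb)
  state$memory[[a]] <- ra$memory
  state$memory[[b]] <- rb$memory

  c_a <- choose_cooperation(expected_cooperation(ra$retrieved, cfg$cold_start))
  c_b <- choose_cooperation(expected_cooperation(rb$retrieved, cfg$cold_start))

  p_a <- cpd_payoff(c_a, c_b, cfg$payoff)
  p_b <- cpd_payoff(c_b, c_a, cfg$payoff)

  d_a <- appraise_emotion(ag$beta_t[a], c_b, c_a)
  d_b <- appraise_emotion(ag$beta_t[b], c_a, c_b)

  state$memory[[a]] <- dplyr::bind_rows(state$memory[[a]], tibble::tibble(
    counterpart_id = b, cooperation = c_b, emotion = d_a,
    initial_strength = encode_strength(d_a, pa),
    encoded_at = as.integer(t), firsthand = TRUE
  ))
  state$memory[[b]] <- dplyr::bind_rows(state$memory[[b]], tibble::tibble(
    counterpart_id = a, cooperation = c_a, emotion = d_b,
    initial_strength = encode_strength(d_b, pb),
    encoded_at = as.integer(t), firsthand = TRUE
  ))

  if (ag$type[a] != "bipolar") ag$mood[a] <- update_mood(ag$mood[a], ag$kappa[a], d_a)
  if (ag$type[b] != "bipolar") ag$mood[b] <- update_mood(ag$mood[b], ag$kappa[b], d_b)
  ag$cumulative_payoff[a] <- ag$cumulative_payoff[a] + p_a
  ag$cumulative_payoff[b] <- ag$cumulative_payoff[b] + p_b
  ag$n_interactions[a] <- ag$n_interactions[a] + 1L
  ag$n_interactions[b] <- ag$n_interactions[b] + 1L
  state$agents <- ag

  state$last_record <- tibble::tibble(
    round = as.integer(t), id_a = a, id_b = b, c_a = c_a, c_b = c_b,
    payoff_a = p_a, payoff_b = p_b, emotion_a = d_a, emotion_b = d_b
  )
  state
}

run_rounds_reference <- function(agents, network, config) {
  n <- nrow(agents)
  agents$mood <- agents$mood0
  agents$beta_t <- agents$beta0
  agents$cumulative_payoff <- 0
  agents$n_interactions <- 0L
  agents$n_active_rounds <- 0L
  state <- list(
    agents = agents,
    memory = replicate(n, empty_traces(), simplify = FALSE),
    config = config
  )
  events <- list()
  omega <- rep(NA_real_, n)
  bip <- which(agents$type == "bipolar")
  for (t in seq_len(config$n_rounds)) {
    if (length(bip) > 0) {
      if ((t - 1) %% config$omega_resample_every == 0) {
        omega[bip] <- resample_omega(state$agents$omega_mean[bip])
      }
      state$agents$mood[bip] <-
        bipolar_mood(t, omega[bip], state$agents$lambda[bip])
      state$agents$beta_t[bip] <-
        bipolar_reward_sensitivity(state$agents$mood[bip], config$beta_max)
    }
    active <- sample_active(state$agents)
    state$agents$n_active_rounds[active] <-
      state$agents$n_active_rounds[active] + 1L
    pairs <- pair_active(network, active)
    if (nrow(pairs) > 0) {
      for (k in seq_len(nrow(pairs))) {
        state <- run_interaction(state, pairs$id_a[k], pairs$id_b[k], t)
        events[[length(events) + 1]] <- state$last_record
        if (config$broadcast) {
          g <- broadcast_gists(state$last_record, network, t)
          for (o in unique(g$owner_id)) {
            state$memory[[o]] <- dplyr::bind_rows(
              state$memory[[o]],
              g[g$owner_id == o, -1, drop = FALSE]
            )
          }
        }
      }
    }
  }
  for (i in seq_len(n)) {
    state$memory[[i]] <-
      purge_traces(state$memory[[i]], config$n_rounds, agent_params(state$agents, i))
  }
  list(
    events = if (length(events)) dplyr::bind_rows(events) else NULL,
    agents = state$agents,
    memory = state$memory
  )
}

stream_seeds <- function(seed, k = 6) {
  (as.integer(seed) + 1000003L * seq_len(k)) %% 2147483647L
}

#' Run a full simulation
#'
#' Spawns the population, wires the social network, and runs the round loop:
#' every round the bipolar rhythm advances (with the angular rate resampled
#' every `omega_resample_every` rounds), agents become active with their
#' drive probability, active agents are matched with active neighbours, each
#' pair interacts (see [run_interaction()]), and interaction gists are
#' broadcast to neighbours. Fully deterministic given `(config, seed)`: the
#' master seed fans out to substreams for population, network, activity,
#' pairing, retrieval/cold-start, and the bipolar rhythm.
#'
#' @param config A [default_config()] object.
#' @param seed Master seed (integer).
#' @param engine `"cpp"` (compiled, fast; the default) or `"reference"`
#'   (pure R, for small configurations). The two implement the same model;
#'   their random streams differ.
#' @return An object of class `mood_sim`: list with `agents` (final per-agent
#'   tibble, including cumulative payoff, interaction/activity counts, final
#'   mood and reward sensitivity), `events` (the full interaction log, one
#'   row per interaction), `network`, `config`, `seed`.
#' @examples
#' \donttest{
#' sim <- run_simulation(default_config(n_agents = 40, n_rounds = 100), seed = 1)
#' summarize_types(sim)
#' }
#' @export
run_simulation <- function(config = default_config(), seed = 1L,
                           engine = c("cpp", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "sim_config"))
  seeds <- stream_seeds(seed)
  agents <- withr::with_seed(seeds[1], spawn_population(config))
  network <- withr::with_seed(seeds[2],
                              build_network(agents, config$depressed_diversity))
  agents <- network$agents

  if (engine == "reference") {
    res <- withr::with_seed(seeds[3], run_rounds_reference(agents, network, config))
    out_agents <- res$agents
    events <- res$events
    extra <- list(memory = res$memory)
  } else {
    type_int <- match(agents$type, c("rational", "manic", "depressed", "bipolar"))
    raw <- sim_run_cpp(
      nrow(agents), type_int, agents$beta0, agents$kappa, agents$mood0,
      agents$lambda, agents$omega_mean, agents$drive, network$adjacency,
      agents$forget_rate, agents$min_strength, agents$grad_neg,
      agents$grad_pos, agents$intercept, agents$mood_dependence,
      config$n_rounds, config$omega_resample_every,
      config$payoff$C, config$payoff$T, config$payoff$D, config$payoff$S,
      config$beta_max,
      identical(config$cold_start, "uniform"),
      if (identical(config$cold_start, "uniform")) 0.5 else config$cold_start,
      config$broadcast,
      seeds[3:6]
    )
    out_agents <- agents
    out_agents$cumulative_payoff <- raw$cumulative_payoff
    out_agents$n_interactions <- raw$n_interactions
    out_agents$n_active_rounds <- raw$n_active_rounds
    out_agents$mood <- raw$final_mood
    out_agents$beta_t <- raw$final_beta
    out_agents$traces_alive <- raw$traces_alive
    events <- tibble::as_tibble(raw$events)
    extra <- list(total_gists = raw$total_gists)
  }

  structure(
    c(list(
      agents = out_agents, events = events, network = network,
      config = config, seed = seed, engine = engine
    ), extra),
    class = "mood_sim"
  )
}

#' @export
print.mood_sim <- function(x, ...) {
  cat(sprintf(
    "<mood_sim> %d agents, %d rounds, %d interactions (seed %d, %s engine)\n",
    nrow(x$agents), x$config$n_rounds,
    if (is.null(x$events)) 0L else nrow(x$events), x$seed, x$engine
  ))
  s <- summarize_types(x)
  print(as.data.frame(s), row.names = FALSE)
  invisible(x)
}
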