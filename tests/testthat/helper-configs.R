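# small societies used across the unit tests; full-scale runs live in
# test-acceptance.R only

small_config <- function(n_agents = 40, n_rounds = 100, ...) {
  default_config(n_agents = n_agents, n_rounds = n_rounds, ...)
}

rational_config <- function(n = 4, rounds = 10, ...) {
  default_config(
    n_agents = n, n_rounds = rounds,
    proportions = c(rational = 1),
    cold_start = 0.5, drive_override = 1, ...
  )
}

# a hand-built network object (path graph 1-2-3) for pairing tests
path_network <- function() {
  agents <- tibble::tibble(
    id = 1:3, type = "rational", drive = 1, target_degree = c(1L, 2L, 1L)
  )
  structure(
    list(
      edges = tibble::tibble(from = c(1L, 2L), to = c(2L, 3L)),
      adjacency = list(2L, c(1L, 3L), 2L),
      agents = agents, pi = 0, dropped_stubs = 0L
    ),
    class = "social_network"
  )
}
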