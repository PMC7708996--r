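test_that("activity sampling follows each agent's drive", {
  ag <- tibble::tibble(id = 1:100, drive = 1)
  expect_equal(sample_active(ag), 1:100)
  ag$drive <- 0
  expect_equal(length(sample_active(ag)), 0)
  ag$drive <- 0.5
  withr::with_seed(1, {
    rate <- mean(replicate(200, length(sample_active(ag)))) / 100
  })
  expect_equal(rate, 0.5, tolerance = 3 * sqrt(0.25 / (200 * 100)) / 0.5)
})

test_that("pairing builds a matching and the path centre is always matched", {
  net <- path_network()
  # only A and B active: one forced pair
  expect_equal(nrow(pair_active(net, c(1L, 2L))), 1)
  # no internal edges among active agents: empty matching
  expect_equal(nrow(pair_active(net, c(1L, 3L))), 0)
  counts <- c(ab = 0, bc = 0)
  withr::with_seed(2, {
    for (i in 1:2000) {
      p <- pair_active(net, 1:3)
      expect_equal(nrow(p), 1)
      expect_true(2L %in% c(p$id_a, p$id_b))
      if (setequal(c(p$id_a, p$id_b), c(1L, 2L))) counts["ab"] <- counts["ab"] + 1
      else counts["bc"] <- counts["bc"] + 1
    }
  })
  # enumeration of the seeded procedure: each pair occurs half the time
  # (first-visited endpoint forces its only neighbour; the centre splits)
  expect_equal(unname(counts["ab"] / 2000), 0.5,
               tolerance = 3 * sqrt(0.25 / 2000) / 0.5)
})

test_that("broadcast writes one neutral gist per outside neighbour", {
  ag <- withr::with_seed(3, spawn_population(small_config()))
  net <- withr::with_seed(4, build_network(ag, 0.25))
  rec <- tibble::tibble(id_a = 1L, id_b = net$adjacency[[1]][1],
                        c_a = 0.3, c_b = 0.8)
  g <- broadcast_gists(rec, net, t = 7)
  n_a <- length(setdiff(net$adjacency[[rec$id_a]], rec$id_b))
  n_b <- length(setdiff(net$adjacency[[rec$id_b]], rec$id_a))
  expect_equal(nrow(g), n_a + n_b)
  expect_true(all(g$emotion == 0))
  expect_false(any(g$firsthand))
  expect_true(all(g$encoded_at == 7L))
  # receivers hear about the *other* participant, at their own intercept
  expect_true(all(g$counterpart_id[g$owner_id %in% net$adjacency[[rec$id_a]]] %in%
                    c(rec$id_b, rec$id_a)))
  expect_equal(g$initial_strength, ag$intercept[g$owner_id])
})

test_that("two cold-start rational agents split the mutual-cooperation midpoint", {
  cfg <- rational_config(n = 2, rounds = 1)
  sim <- run_simulation(cfg, seed = 1)
  expect_equal(nrow(sim$events), 1)
  expect_equal(sim$events$c_a, 0.5)
  expect_equal(sim$events$c_b, 0.5)
  expect_equal(sim$events$payoff_a, 2.5)
  expect_equal(sim$events$payoff_b, 2.5)
  expect_equal(sim$events$emotion_a, 0)
  expect_equal(sim$agents$cumulative_payoff, c(2.5, 2.5))
})

test_that("the reference and compiled engines agree on a deterministic society", {
  cfg <- rational_config(n = 4, rounds = 5)
  fast <- run_simulation(cfg, seed = 3, engine = "cpp")
  ref <- run_simulation(cfg, seed = 3, engine = "reference")
  # with fixed 0.5 cold start a rational society is pinned at c = 0.5
  for (sim in list(fast, ref)) {
    expect_true(all(sim$events$c_a == 0.5 & sim$events$c_b == 0.5))
    expect_true(all(sim$events$payoff_a == 2.5))
    expect_equal(sum(sim$agents$cumulative_payoff), 2.5 * 2 * nrow(sim$events))
    expect_true(all(sim$agents$mood == 0))
  }
  # full participation on a complete 4-clique: two pairs every round
  expect_equal(nrow(fast$events), 2 * 5)
  expect_equal(nrow(ref$events), 2 * 5)
})

test_that("the same config and seed reproduce the event log exactly", {
  cfg <- default_config(n_agents = 60, n_rounds = 150)
  a <- run_simulation(cfg, seed = 11)
  b <- run_simulation(cfg, seed = 11)
  expect_identical(a$events, b$events)
  expect_identical(a$agents, b$agents)
  c <- run_simulation(cfg, seed = 12)
  expect_false(identical(a$events, c$events))
})

test_that("the event log reconciles with the payoff ledger and the closed forms", {
  cfg <- default_config(n_agents = 60, n_rounds = 200)
  sim <- run_simulation(cfg, seed = 5)
  ev <- sim$events
  ag <- sim$agents
  k <- cfg$payoff

  # conservation: online accumulators equal the log
  expect_equal(sum(ag$cumulative_payoff), sum(ev$payoff_a) + sum(ev$payoff_b),
               tolerance = 1e-12)
  by_id <- summarize_events(ev, ag)
  online <- summarize_types(sim)
  expect_equal(by_id$mean_payoff[order(by_id$type)],
               online$mean_payoff[order(online$type)], tolerance = 1e-12)

  # payoffs recompute exactly from the logged cooperation levels
  expect_equal(ev$payoff_a, cpd_payoff(ev$c_a, ev$c_b, k), tolerance = 1e-12)
  expect_equal(ev$payoff_b, cpd_payoff(ev$c_b, ev$c_a, k), tolerance = 1e-12)

  # emotions recompute from constant reward sensitivity for non-bipolar agents
  non_bip <- ag$type[ev$id_a] != "bipolar"
  expect_equal(ev$emotion_a[non_bip],
               appraise_emotion(ag$beta0[ev$id_a[non_bip]],
                                ev$c_b[non_bip], ev$c_a[non_bip]),
               tolerance = 1e-12)

  # every interaction is between neighbours
  adj <- sim$network$adjacency
  expect_true(all(mapply(function(a1, b1) b1 %in% adj[[a1]], ev$id_a, ev$id_b)))
  # no agent appears twice in one round
  per_round <- split(c(ev$id_a, ev$id_b), c(ev$round, ev$round))
  expect_true(all(vapply(per_round, function(x) !anyDuplicated(x), TRUE)))
})

test_that("moods stay bounded and bipolar sensitivity tracks the rhythm map", {
  sim <- run_simulation(small_config(n_rounds = 200), seed = 9)
  expect_true(all(abs(sim$agents$mood) <= 1))
  bip <- sim$agents[sim$agents$type == "bipolar", ]
  expect_equal(bip$beta_t, bipolar_reward_sensitivity(bip$mood, 10),
               tolerance = 1e-12)
  rat <- sim$agents[sim$agents$type == "rational", ]
  expect_true(all(rat$mood == 0))
})

test_that("per-agent activity converges to the trait drive", {
  cfg <- default_config(n_agents = 60, n_rounds = 1000)
  sim <- run_simulation(cfg, seed = 13)
  rate <- sim$agents$n_active_rounds / cfg$n_rounds
  se <- sqrt(sim$agents$drive * (1 - sim$agents$drive) / cfg$n_rounds)
  expect_true(all(abs(rate - sim$agents$drive) <= 4 * se + 1e-9))
})

test_that("disabling broadcast removes secondhand traces", {
  cfg_on <- small_config(cold_start = 0.5)
  cfg_off <- small_config(cold_start = 0.5, broadcast = FALSE)
  on <- run_simulation(cfg_on, seed = 21)
  off <- run_simulation(cfg_off, seed = 21)
  expect_gt(on$total_gists, 0)
  expect_equal(off$total_gists, 0)
  expect_lt(sum(off$agents$traces_alive), sum(on$agents$traces_alive))
})
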