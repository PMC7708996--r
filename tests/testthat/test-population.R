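test_that("drive follows the min-max rescaling of trait sensitivity", {
  expect_equal(drive_of(1), 0.5)
  expect_equal(drive_of(0.5), 0.25)
  expect_equal(drive_of(10, 10), 1)
  expect_error(drive_of(-1), "beta0")
})

test_that("target degree scales like drive and is capped at n - 1", {
  expect_equal(degree_of(1, 10, 200), 100L)
  expect_equal(degree_of(0.5, 10, 200), 50L)
  expect_equal(degree_of(10, 10, 200), 199L)  # raw 200 capped
  b <- seq(0, 10, by = 0.5)
  expect_true(all(diff(drive_of(b, 10)) >= 0))
  expect_true(all(diff(degree_of(b, 10, 200)) >= 0))
})

test_that("a pure rational society gets the textbook attributes", {
  cfg <- default_config(n_agents = 10, proportions = c(rational = 1))
  ag <- withr::with_seed(1, spawn_population(cfg))
  expect_equal(nrow(ag), 10)
  expect_true(all(ag$beta0 == 1))
  expect_true(all(ag$mood0 == 0))
  expect_true(all(ag$drive == 0.5))
  expect_true(all(ag$target_degree == 5L))
  expect_true(all(ag$kappa == 0))
})

test_that("equal proportions split the population equally", {
  ag <- withr::with_seed(2, spawn_population(default_config()))
  expect_equal(unname(table(ag$type)[c("rational", "manic", "depressed", "bipolar")]),
               rep(50L, 4), ignore_attr = TRUE)
})

test_that("spawned attributes satisfy the per-type trait table across seeds", {
  for (s in 1:5) {
    ag <- withr::with_seed(s, spawn_population(default_config()))
    rat <- ag[ag$type == "rational", ]
    man <- ag[ag$type == "manic", ]
    dep <- ag[ag$type == "depressed", ]
    bip <- ag[ag$type == "bipolar", ]
    expect_true(all(rat$beta0 == 1 & rat$mood0 == 0 & rat$kappa == 0))
    expect_true(all(man$beta0 > 1 & man$beta0 <= 10))
    expect_true(all(man$mood0 >= 0 & man$mood0 <= 1))
    expect_true(all(man$drive >= 0.5 & man$target_degree >= 100))
    expect_true(all(man$kappa == 0.1))
    expect_true(all(dep$beta0 >= 0 & dep$beta0 < 1))
    expect_true(all(dep$mood0 >= -1 & dep$mood0 < 0))
    expect_true(all(dep$drive < 0.5 & dep$target_degree <= 100))
    expect_true(all(dep$kappa == 0.1))
    expect_true(all(is.na(bip$kappa)))
    expect_true(all(bip$lambda >= -1 & bip$lambda <= 1))
    expect_true(all(bip$mood0 >= -1 & bip$mood0 <= 1))
    expect_equal(bip$beta0, bipolar_reward_sensitivity(bip$mood0, 10))
    # drive and degree derive from beta0 for every type
    expect_equal(ag$drive, drive_of(ag$beta0, 10))
    expect_equal(ag$target_degree, degree_of(ag$beta0, 10, 200))
  }
})

test_that("configuration validation rejects malformed inputs", {
  expect_error(default_config(proportions = c(rational = 0.6, manic = 0.6)),
               "sum to 1")
  expect_error(default_config(proportions = c(0.5, 0.5)), "named")
  expect_error(default_config(cold_start = 1.4), "cold_start")
})

test_that("per-type memory overrides reach only the targeted type", {
  cfg <- default_config(
    memory_by_type = list(depressed = memory_params(grad_pos = 40))
  )
  ag <- withr::with_seed(3, spawn_population(cfg))
  expect_true(all(ag$grad_pos[ag$type == "depressed"] == 40))
  expect_true(all(ag$grad_pos[ag$type != "depressed"] == 80))
})

test_that("yaml round trip preserves the configuration", {
  cfg <- default_config(n_agents = 60, n_rounds = 500,
                        memory = memory_params(forget_rate = 0.1))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$n_agents, 60L)
  expect_equal(back$n_rounds, 500L)
  expect_equal(back$memory$forget_rate, 0.1)
  expect_equal(back$proportions, cfg$proportions)
})
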