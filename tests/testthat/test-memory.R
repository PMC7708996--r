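trace_row <- function(phi0, enc = 0L, emotion = 0, coop = 0.5, cp = 1L) {
  tibble::tibble(
    counterpart_id = cp, cooperation = coop, emotion = emotion,
    initial_strength = phi0, encoded_at = as.integer(enc), firsthand = TRUE
  )
}

test_that("encoding strength is piecewise linear in emotion", {
  p_unb <- memory_params(grad_neg = 80, grad_pos = 80, intercept = 10)
  p_pos <- memory_params(grad_neg = 40, grad_pos = 80, intercept = 10)
  p_negb <- memory_params(grad_neg = 80, grad_pos = 40, intercept = 10)
  expect_equal(encode_strength(0, p_unb), 10)
  expect_equal(encode_strength(-1, p_negb), 90)
  expect_equal(encode_strength(0.5, p_negb), 30)
  # monotone away from neutral, charged events encoded more strongly
  e <- seq(-1, 1, by = 0.05)
  s <- encode_strength(e, p_pos)
  expect_true(all(diff(s[e <= 0]) <= 0))
  expect_true(all(diff(s[e >= 0]) >= 0))
  expect_true(all(encode_strength(c(-1, 1), p_unb) > encode_strength(0, p_unb)))
  expect_true(all(s >= p_pos$intercept & s <= max(40, 80) + 10))
})

test_that("strength decays exponentially from the last encoding or refresh", {
  p <- memory_params(forget_rate = 0.001)
  expect_equal(strength_at(trace_row(90), 0, p), 90)
  expect_equal(strength_at(trace_row(90), 1000, p), 90 * exp(-1), tolerance = 1e-9)
  expect_equal(strength_at(trace_row(90), 1000, p), 33.1091, tolerance = 1e-4)
  p10 <- memory_params(forget_rate = 10)
  expect_equal(strength_at(trace_row(90), 1, p10), 0.004086, tolerance = 1e-3)
  # a refreshed clock re-anchors elapsed time
  expect_equal(strength_at(trace_row(90, enc = 500L), 1500, p), 90 * exp(-1))
  expect_error(strength_at(trace_row(90, enc = 10L), 5, p), "precedes")
})

test_that("availability duration matches the closed-form lifetime bound", {
  p <- memory_params(forget_rate = 1e-4, min_strength = 1)
  expect_equal(availability_duration(1, p), 0)
  expect_equal(availability_duration(10, p), 1e4 * log(10), tolerance = 1e-9)
  expect_gt(availability_duration(10, p), 2000) # perfect-memory regime
  p10 <- memory_params(forget_rate = 10, min_strength = 1)
  expect_lt(availability_duration(90, p10), 1)  # no-memory regime
  expect_error(availability_duration(0.5, p), "min_strength")
})

test_that("brute-force decay scanning agrees with the lifetime bound", {
  withr::with_seed(7, {
    for (i in 1:1000) {
      phi_min <- runif(1, 0.5, 2)
      phi0 <- phi_min * exp(runif(1, 0.01, 6))
      theta <- runif(1, 0.05, 2)
      p <- memory_params(
        forget_rate = theta, min_strength = phi_min,
        intercept = phi_min * 2 + phi0
      )
      d <- availability_duration(phi0, p)
      # first integer time the scanned strength drops below threshold
      tr <- trace_row(phi0)
      t_scan <- 0
      while (strength_at(tr, t_scan, p) >= phi_min) t_scan <- t_scan + 1
      # first failure time lies in (d, d + 1]
      expect_gt(t_scan, d - 1e-9)
      expect_lte(t_scan - d, 1 + 1e-9)
      expect_gte(strength_at(tr, floor(d), p), phi_min * (1 - 1e-9))
    }
  })
})

test_that("purge deletes exactly the sub-threshold traces and is idempotent", {
  p <- memory_params(forget_rate = 10, min_strength = 1)
  expect_equal(nrow(purge_traces(empty_traces(), 5, p)), 0)
  # phi0 = 10, theta = 10, 1 round elapsed -> strength ~ 4.5e-4 < 1
  expect_equal(nrow(purge_traces(trace_row(10), 1, p)), 0)
  expect_equal(nrow(purge_traces(trace_row(10), 0, p)), 1)
  mixed <- dplyr::bind_rows(trace_row(10, enc = 0L), trace_row(10, enc = 5L))
  once <- purge_traces(mixed, 5, p)
  expect_equal(once$encoded_at, 5L)
  expect_identical(purge_traces(once, 5, p), once)
})

test_that("retrieval probability is the triangular mood-congruence kernel", {
  expect_equal(retrieval_probability(-0.7, 0.9, 0), 1)   # gamma 0: not selective
  expect_equal(retrieval_probability(0.5, 0, 1), 0.5)
  expect_equal(retrieval_probability(-0.8, 0.8, 10), 0)
  e <- seq(-1, 1, by = 0.1)
  p <- retrieval_probability(e, 0.3, 2)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(which.max(p), which.min(abs(e - 0.3)))
  expect_error(retrieval_probability(0, 0, -1), "gamma")
})

test_that("retrieval filters by counterpart, refreshes hits, never adds traces", {
  p <- memory_params(mood_dependence = 0)
  mem <- dplyr::bind_rows(
    trace_row(90, enc = 0L, emotion = -1, cp = 1L),
    trace_row(10, enc = 0L, emotion = 0, cp = 1L),
    trace_row(90, enc = 0L, emotion = 1, cp = 2L)
  )
  out <- withr::with_seed(1, retrieve_traces(mem, 1L, mood = 0, t = 50, p))
  # gamma 0: both counterpart-1 traces retrieved and refreshed
  expect_equal(nrow(out$retrieved), 2)
  expect_true(all(out$retrieved$encoded_at == 50L))
  expect_equal(nrow(out$memory), nrow(mem))
  expect_equal(out$memory$encoded_at, c(50L, 50L, 0L))
  # unknown counterpart: empty set, store untouched
  none <- retrieve_traces(mem, 9L, 0, 50, p)
  expect_equal(nrow(none$retrieved), 0)
  expect_identical(none$memory, mem)
})

test_that("empirical retrieval frequencies match the kernel probabilities", {
  p <- memory_params(mood_dependence = 10)
  mem <- dplyr::bind_rows(
    trace_row(90, emotion = -1, cp = 1L),
    trace_row(10, emotion = 0, cp = 1L),
    trace_row(90, emotion = 1, cp = 1L)
  )
  hits <- c(0, 0, 0)
  n_rep <- 2000
  withr::with_seed(11, {
    for (i in seq_len(n_rep)) {
      out <- retrieve_traces(mem, 1L, mood = 1, t = 0, p)
      hits <- hits + as.numeric(c(-1, 0, 1) %in% out$retrieved$emotion)
    }
  })
  # strong mood dependence at mood 1 keeps only the emotion-1 trace
  expect_equal(hits / n_rep, c(0, 0, 1))

  # intermediate probabilities: binomial check at 4 s.e.
  p2 <- memory_params(mood_dependence = 0.8)
  expected <- retrieval_probability(c(-1, 0, 1), 0.3, 0.8)
  hits <- c(0, 0, 0)
  withr::with_seed(12, {
    for (i in seq_len(n_rep)) {
      out <- retrieve_traces(mem, 1L, mood = 0.3, t = 0, p2)
      hits <- hits + as.numeric(c(-1, 0, 1) %in% out$retrieved$emotion)
    }
  })
  se <- sqrt(expected * (1 - expected) / n_rep)
  expect_true(all(abs(hits / n_rep - expected) <= 4 * se + 1e-12))
})

test_that("a trace refreshed every round outlives its unrefreshed bound", {
  p <- memory_params(forget_rate = 0.5, min_strength = 1, intercept = 10,
                     mood_dependence = 0)
  # unrefreshed lifetime ~ ln(10)/0.5 ~ 4.6 rounds
  mem <- trace_row(10, enc = 0L, cp = 1L)
  withr::with_seed(3, {
    for (t in 1:50) {
      mem <- purge_traces(mem, t, p)
      mem <- retrieve_traces(mem, 1L, 0, t, p)$memory
    }
  })
  expect_equal(nrow(mem), 1)              # still alive at t = 50
  expect_equal(mem$encoded_at, 50L)
  # without refresh the same trace is long gone
  expect_equal(nrow(purge_traces(trace_row(10), 50, p)), 0)
})

test_that("memory parameter validation enforces the structural constraints", {
  expect_error(memory_params(forget_rate = 0))
  expect_error(memory_params(min_strength = 20, intercept = 10))
  expect_error(memory_params(grad_neg = 0))
})
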