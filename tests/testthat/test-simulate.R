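test_that("the simulator is deterministic given a seed", {
  cfg <- sim_config(n_bouts = 5, seed = 101)
  d1 <- simulate_dyad(walker_params(), cfg)
  d2 <- simulate_dyad(walker_params(), cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_step_events(d1, f1); write_step_events(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- null_dataset(sim_config(n_bouts = 3, seed = 55))
  d4 <- null_dataset(sim_config(n_bouts = 3, seed = 55))
  expect_identical(d3$time, d4$time)
})

test_that("uncoupled noiseless walkers are perfect metronomes", {
  p <- walker_params(motor_noise_sd = 0, drift_sd = 0,
                     coupling_front_from_hind = 0,
                     coupling_hind_from_front = 0, initial_offset = 0.2)
  d <- simulate_dyad(p, sim_config(n_bouts = 1, bout_duration_range = c(18, 18),
                                   seed = 1))
  of <- bout_onsets(d, "bout01", "front")
  oh <- bout_onsets(d, "bout01", "hind")
  expect_equal(diff(of), rep(0.89, length(of) - 1), tolerance = 1e-9)
  expect_equal(oh - of[seq_along(oh)], rep(0.2, length(oh)), tolerance = 1e-9)

  span <- c(0, max(d$time))
  sf <- smooth_series(events_to_series(of, 100, span))
  sh <- smooth_series(events_to_series(oh, 100, span))
  lag <- cross_correlation_lag(sf, sh)$lag
  expect_lt(abs(lag - 0.2), 1 / 48 + 0.011)
})

test_that("symmetric coupling 0.25/0.25 halves the asynchrony each step", {
  p <- walker_params(motor_noise_sd = 0, drift_sd = 0, initial_offset = 0.2)
  d <- simulate_dyad(p, sim_config(n_bouts = 1, bout_duration_range = c(12, 12),
                                   seed = 2))
  of <- bout_onsets(d, "bout01", "front")
  oh <- bout_onsets(d, "bout01", "hind")
  m <- min(length(of), length(oh))
  asyn <- abs(of[1:m] - oh[1:m])
  # geometric convergence of the closed-form map d_{k+1} = 0.5 d_k
  # (millisecond rounding floors the tail)
  expected <- 0.2 * 0.5^(0:(m - 1))
  expect_true(all(abs(asyn - expected) <= 0.0015))
})

test_that("full gains with zero noise stay valid (bounded asynchrony)", {
  p <- walker_params(motor_noise_sd = 0, drift_sd = 0,
                     coupling_front_from_hind = 1,
                     coupling_hind_from_front = 1, initial_offset = 0.1)
  d <- simulate_dyad(p, sim_config(n_bouts = 1, bout_duration_range = c(15, 15),
                                   seed = 3))
  expect_s3_class(d, "step_dataset")
  of <- bout_onsets(d, "bout01", "front")
  oh <- bout_onsets(d, "bout01", "hind")
  m <- min(length(of), length(oh))
  expect_lte(max(abs(of[1:m] - oh[1:m])), 0.1 + 1e-9)
})

test_that("realized step statistics sit in the empirical band at defaults", {
  d <- simulate_dyad(walker_params(), sim_config(n_bouts = 100, seed = 500))
  steps <- unlist(lapply(bout_ids(d), function(b)
    c(diff(bout_onsets(d, b, "front")), diff(bout_onsets(d, b, "hind")))))
  expect_gt(mean(steps), 0.8)
  expect_lt(mean(steps), 1.0)
  expect_gt(sd(steps), 0.1)
  expect_lt(sd(steps), 0.2)
  durs <- bout_durations(d)
  expect_gte(min(durs), 0)
  expect_lte(max(durs), 48)
})

test_that("synchrony of relative phase is monotone in symmetric coupling", {
  rbar_at_gain <- function(g, seed) {
    p <- walker_params(coupling_front_from_hind = g,
                       coupling_hind_from_front = g, initial_offset = 0.3)
    d <- simulate_dyad(p, sim_config(n_bouts = 80,
                                     bout_duration_range = c(10, 20),
                                     seed = seed))
    rel <- unlist(lapply(bout_ids(d), function(b) {
      of <- bout_onsets(d, b, "front"); oh <- bout_onsets(d, b, "hind")
      vapply(of, function(t) {
        dmin <- oh[which.min(abs(oh - t))] - t
        360 * dmin / 0.89
      }, numeric(1))
    }))
    circular_summary(rel)$R_bar
  }
  gains <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
  rbars <- vapply(seq_along(gains), function(i)
    rbar_at_gain(gains[i], seed = 600 + i), numeric(1))
  expect_true(all(diff(rbars) > -0.05))
  expect_gt(rbars[length(rbars)], rbars[1])
})

test_that("null datasets have unlocked phases", {
  d <- null_dataset(sim_config(n_bouts = 60, seed = 777))
  rel <- unlist(lapply(bout_ids(d), function(b) {
    of <- bout_onsets(d, b, "front"); oh <- bout_onsets(d, b, "hind")
    vapply(of, function(t) 360 * (oh[which.min(abs(oh - t))] - t) / 0.89,
           numeric(1))
  }))
  expect_lt(circular_summary(rel)$R_bar, 0.35)
})
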