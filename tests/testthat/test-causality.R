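test_that("VAR fit satisfies the normal equations and recovers known dynamics", {
  set.seed(21)
  # white-noise pair: coefficients near zero
  f0 <- fit_var(rnorm(500), rnorm(500), p = 1)
  expect_true(all(abs(f0$coef[-1, ]) < 0.15))
  # residuals orthogonal to regressors
  x <- sim_ar1(400, 0.8); y <- rnorm(400)
  f1 <- fit_var(x, y, p = 2)
  d <- stepsync:::var_design(x, y, 2)
  ortho <- crossprod(d$X, f1$residuals)
  expect_lt(max(abs(ortho)) / max(abs(crossprod(d$X, d$Y))), 1e-8)

  # AR(1) own-lag recovery
  set.seed(22)
  f2 <- fit_var(sim_ar1(2000, 0.8), rnorm(2000), p = 1)
  expect_equal(unname(f2$coef["x.l1", "x"]), 0.8, tolerance = 0.05)

  # cross-driven pair: gain 0.6 at lag 2 lands on the right coefficient
  set.seed(23)
  cd <- sim_cross_driven(2000, gain = 0.6, lag = 2)
  f3 <- fit_var(cd$x, cd$y, p = 3)
  expect_equal(unname(f3$coef["x.l2", "y"]), 0.6, tolerance = 0.05)
  expect_lt(abs(f3$coef["x.l1", "y"]), 0.1)

  expect_error(fit_var(rep(1, 100), rnorm(100), p = 1), "degenerate")
  expect_error(fit_var(rnorm(10), rnorm(10), p = 5), "too short")
})

test_that("AIC lag selection concentrates on the generative order", {
  set.seed(31)
  hits <- replicate(10, {
    x <- numeric(600)
    for (t in 3:600) x[t] <- 0.5 * x[t - 1] - 0.4 * x[t - 2] + rnorm(1)
    sel <- select_var_lag(x, rnorm(600), max_lag = 0.08, rate = 100)
    sel$optimal_p
  })
  expect_gte(sum(hits == 2), 7)

  # near-noiseless AR(1): first-order model suffices
  set.seed(32)
  x1 <- sim_ar1(500, 0.9, sd = 1e-3)
  x1[1] <- 1
  sel1 <- select_var_lag(x1, sim_ar1(500, 0.5, sd = 1e-3) + rnorm(500, 0, 1e-3),
                         max_lag = 0.05, rate = 100)
  expect_equal(sel1$optimal_p, 1L)
  expect_equal(sel1$optimal_lag, sel1$candidate_lags[sel1$optimal_p])

  expect_warning(select_var_lag(rnorm(40), rnorm(40), max_lag = 0.3,
                                rate = 100),
                 "truncated")
})

test_that("Granger F matches the textbook restricted/full OLS formula", {
  set.seed(41)
  cd <- sim_cross_driven(400, gain = 0.5, lag = 2)
  p <- 3
  g <- granger_classify(cd$x, cd$y, lag = p / 100, rate = 100)

  # independent oracle: two lm() fits and the F ratio computed by hand
  n <- length(cd$x)
  rows <- (p + 1):n
  emb_x <- sapply(1:p, function(j) cd$x[rows - j])
  emb_y <- sapply(1:p, function(j) cd$y[rows - j])
  full <- lm(cd$y[rows] ~ emb_y + emb_x)
  restr <- lm(cd$y[rows] ~ emb_y)
  rss_f <- sum(resid(full)^2); rss_r <- sum(resid(restr)^2)
  f_oracle <- ((rss_r - rss_f) / p) / (rss_f / (length(rows) - 2 * p - 1))
  expect_equal(g$stat_f2h, f_oracle, tolerance = 1e-8)
  p_oracle <- pf(f_oracle, p, length(rows) - 2 * p - 1, lower.tail = FALSE)
  expect_equal(g$p_front_to_hind, p_oracle, tolerance = 1e-10)
})

test_that("Granger F and p agree with lmtest::grangertest", {
  skip_if_not_installed("lmtest")
  set.seed(42)
  cd <- sim_cross_driven(300, gain = 0.4, lag = 1, phi = 0.6)
  for (p in c(1, 2, 4)) {
    g <- granger_classify(cd$x, cd$y, lag = p / 100, rate = 100)
    ref <- lmtest::grangertest(cd$y ~ cd$x, order = p)
    expect_equal(g$stat_f2h, ref$F[2], tolerance = 1e-6)
    expect_equal(g$p_front_to_hind, ref$`Pr(>F)`[2], tolerance = 1e-6)
  }
})

test_that("swapping the series swaps the directional tests exactly", {
  set.seed(43)
  cd <- sim_cross_driven(300, gain = 0.5, lag = 2)
  g_ab <- granger_classify(cd$x, cd$y, lag = 0.02, rate = 100)
  g_ba <- granger_classify(cd$y, cd$x, lag = 0.02, rate = 100)
  expect_identical(g_ab$p_front_to_hind, g_ba$p_hind_to_front)
  expect_identical(g_ab$stat_f2h, g_ba$stat_h2f)
  expect_identical(g_ab$p_hind_to_front, g_ba$p_front_to_hind)
})

test_that("classification follows the two directional tests", {
  set.seed(44)
  cd <- sim_cross_driven(600, gain = 0.8, lag = 1, sd = 0.3)
  g <- granger_classify(cd$x, cd$y, lag = 0.02, rate = 100)
  expect_equal(g$classification, "front_leads")
  expect_lt(g$p_front_to_hind, 0.05)

  g_none <- granger_classify(rep(c(1, 0), 100), rnorm(200), lag = 0.02,
                             rate = 100)
  expect_type(g_none$classification, "character")

  g_deg <- granger_classify(rep(1, 200), rnorm(200), lag = 0.02, rate = 100)
  expect_equal(g_deg$classification, "none")
  expect_true(g_deg$degenerate)
})

test_that("type-I error on white noise is near the nominal level", {
  set.seed(45)
  rej <- replicate(400, {
    g <- granger_classify(rnorm(150), rnorm(150), lag = 0.02, rate = 100)
    g$p_front_to_hind < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("event-domain leadership test is seeded, symmetric, and guards short bouts", {
  d <- simulate_dyad(walker_params(coupling_front_from_hind = 0,
                                   coupling_hind_from_front = 1,
                                   motor_noise_sd = 0.01),
                     sim_config(n_bouts = 1, bout_duration_range = c(25, 25),
                                seed = 51))
  of <- bout_onsets(d, "bout01", "front")
  oh <- bout_onsets(d, "bout01", "hind")
  g1 <- granger_events(of, oh, seed = 7)
  g2 <- granger_events(of, oh, seed = 7)
  expect_identical(g1$p_front_to_hind, g2$p_front_to_hind)
  expect_equal(g1$classification, "front_leads")
  expect_lt(g1$p_front_to_hind, 0.05)

  # swapping the subjects swaps the two directional F statistics exactly
  g_sw <- granger_events(oh, of, seed = 7)
  expect_equal(g_sw$stat_h2f, g1$stat_f2h, tolerance = 1e-12)
  expect_equal(g_sw$stat_f2h, g1$stat_h2f, tolerance = 1e-12)
  expect_equal(g_sw$classification, "hind_leads")

  # bouts with too few steps are degenerate, not errors
  g_short <- granger_events(of[1:5], oh[1:5])
  expect_true(g_short$degenerate)
  expect_equal(g_short$classification, "none")
})

test_that("event-domain test favours the true leader at moderate coupling", {
  d <- simulate_dyad(walker_params(coupling_front_from_hind = 0,
                                   coupling_hind_from_front = 0.5),
                     sim_config(n_bouts = 60,
                                bout_duration_range = c(15, 40), seed = 52))
  cls <- vapply(seq_len(60), function(i) {
    b <- sprintf("bout%02d", i)
    granger_events(bout_onsets(d, b, "front"), bout_onsets(d, b, "hind"),
                   seed = 400 + i)$classification
  }, character(1))
  n_front <- sum(cls == "front_leads"); n_hind <- sum(cls == "hind_leads")
  expect_gt(n_front, n_hind)
  expect_lt(binom.test(n_front, n_front + n_hind, 0.5,
                       alternative = "greater")$p.value, 0.01)
})
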