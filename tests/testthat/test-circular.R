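test_that("phase angles follow the modular map and anchor at zero", {
  expect_equal(as.numeric(to_phase_angles(c(0, 0.89, 1.78), 0.89)),
               c(0, 0, 0), tolerance = 1e-9)
  expect_equal(as.numeric(to_phase_angles(c(0, 1.335), 0.89)),
               c(0, 180), tolerance = 1e-9)
  # linear drift of +0.0445 s per step on T = 0.89 advances 18 deg per step
  onsets <- cumsum(c(0, rep(0.89 + 0.0445, 5)))
  ang <- as.numeric(to_phase_angles(onsets, 0.89))
  expect_equal(ang, (0:5) * 18, tolerance = 1e-6)
  expect_error(to_phase_angles(c(0, 1), 0), "period")
})

test_that("phase angles are invariant to adding whole periods", {
  onsets <- c(0.3, 0.95, 1.61, 2.4)
  base <- as.numeric(to_phase_angles(onsets, 0.89, t0 = 0.3))
  for (k in c(1, 5, -2)) {
    shifted <- as.numeric(to_phase_angles(onsets + k * 0.89, 0.89,
                                          t0 = 0.3 + k * 0.89))
    expect_equal(shifted, base, tolerance = 1e-6)
  }
})

test_that("circular summary matches brute-force resultant computation", {
  s <- circular_summary(rep(45, 10))
  expect_equal(s$mean_angle, 45)
  expect_equal(s$R_bar, 1)
  expect_equal(s$circ_sd, 0)

  s2 <- circular_summary(c(0, 90, 180, 270))
  expect_equal(s2$R_bar, 0, tolerance = 1e-12)

  set.seed(42)
  ang <- (rnorm(200, 20, 30)) %% 360
  s3 <- circular_summary(ang)
  oracle <- brute_resultant(ang)
  expect_equal(s3$R_bar, oracle$R_bar, tolerance = 1e-12)
  expect_equal(s3$mean_angle, oracle$mean_angle, tolerance = 1e-9)
  expect_equal(s3$circ_sd, sqrt(-2 * log(oracle$R_bar)) * 180 / pi,
               tolerance = 1e-9)
  expect_error(circular_summary(10), "at least 2")
})

test_that("rotation shifts the mean angle and nothing else", {
  set.seed(7)
  ang <- (rnorm(150, 120, 40)) %% 360
  s0 <- circular_summary(ang)
  for (rot in c(30, 123.4, 300)) {
    s1 <- circular_summary((ang + rot) %% 360)
    expect_equal(s1$mean_angle, (s0$mean_angle + rot) %% 360,
                 tolerance = 1e-6)
    expect_equal(s1$R_bar, s0$R_bar, tolerance = 1e-12)
    expect_equal(s1$rayleigh_p, s0$rayleigh_p, tolerance = 1e-12)
  }
})

test_that("Rayleigh test is calibrated under uniformity and powerful under concentration", {
  set.seed(314)
  p_null <- replicate(400, circular_summary(runif(50, 0, 360))$rayleigh_p)
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 0.035)
  set.seed(315)
  p_conc <- replicate(50, circular_summary((rnorm(50, 0, 30)) %% 360)$rayleigh_p)
  expect_true(all(p_conc < 0.001))
})

test_that("Watson-Williams ANOVA separates distinct mean directions", {
  set.seed(5)
  g_same <- (rnorm(60, 10, 15)) %% 360
  res_same <- circular_anova(list(g_same, g_same))
  expect_equal(res_same$F, 0, tolerance = 1e-9)
  expect_equal(res_same$p, 1, tolerance = 1e-9)
  expect_equal(res_same$df_between, 1L)
  expect_equal(res_same$df_within, 118L)

  g0 <- (rnorm(40, 0, 10)) %% 360
  g90 <- (rnorm(40, 90, 10)) %% 360
  res <- circular_anova(list(g0, g90))
  expect_lt(res$p, 0.001)
  expect_false(res$low_concentration)

  flat <- circular_anova(list(runif(30, 0, 360), runif(30, 0, 360)))
  expect_true(flat$low_concentration)
  expect_error(circular_anova(list(g0)), ">= 2 groups")
})

test_that("Watson-Williams p agrees with a permutation oracle on small groups", {
  set.seed(2024)
  g1 <- (rnorm(15, 0, 25)) %% 360
  g2 <- (rnorm(15, 22, 25)) %% 360
  p_ww <- circular_anova(list(g1, g2))$p
  p_perm <- ww_permutation_p(list(g1, g2), n_perm = 4000)
  expect_lt(abs(p_ww - p_perm), 0.02)
})

test_that("circular correlation hits its analytic anchors", {
  set.seed(9)
  a <- (rnorm(50, 90, 40)) %% 360
  r_id <- circular_correlation(a, a, n_boot = 50)
  expect_equal(r_id$r_js, 1, tolerance = 1e-12)
  r_neg <- circular_correlation(a, (-a) %% 360, n_boot = 50)
  expect_equal(r_neg$r_js, -1, tolerance = 1e-12)
  expect_error(circular_correlation(c(0, 10), c(0, 10)), "at least 3")
})

test_that("circular correlation is invariant under rotation of either sample", {
  set.seed(10)
  a <- (rnorm(80, 0, 30)) %% 360
  b <- (a + rnorm(80, 0, 20)) %% 360
  r0 <- circular_correlation(a, b, n_boot = 10)$r_js
  expect_equal(circular_correlation((a + 77) %% 360, b, n_boot = 10)$r_js,
               r0, tolerance = 1e-9)
  expect_equal(circular_correlation(a, (b + 191) %% 360, n_boot = 10)$r_js,
               r0, tolerance = 1e-9)
})

test_that("circular correlation null is tight and the bootstrap is seeded", {
  set.seed(11)
  r_null <- circular_correlation(runif(1000, 0, 360), runif(1000, 0, 360),
                                 n_boot = 20)
  expect_lt(abs(r_null$r_js), 0.1)
  expect_gt(r_null$p, 0.001)

  set.seed(12)
  a <- (rnorm(60, 0, 30)) %% 360
  b <- (a + rnorm(60, 0, 25)) %% 360
  r1 <- circular_correlation(a, b, n_boot = 200, seed = 123)
  r2 <- circular_correlation(a, b, n_boot = 200, seed = 123)
  expect_identical(r1$ci95, r2$ci95)
  expect_lte(r1$ci95[1], r1$r_js + 1e-9)
  expect_gte(r1$ci95[2], r1$r_js - 1e-9)
  # strong dependence is detected
  expect_lt(r1$p, 0.001)
})
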