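# Shared fixture builders for the test suite.

# A perfect isochronous impulse train as a smoothed pulse series.
perfect_train <- function(period, n_beats, rate = 100, smooth = TRUE) {
  onsets <- seq(0, by = period, length.out = n_beats)
  s <- events_to_series(onsets, rate = rate, span = c(0, max(onsets)))
  if (smooth) smooth_series(s) else s
}

# Tiny two-subject dataset: both walkers on a fixed grid.
tiny_dataset <- function(period = 0.9, n_steps = 6, offset = 0.02,
                         bout = "b1") {
  tf <- round(seq(0, by = period, length.out = n_steps), 3)
  th <- round(tf + offset, 3)
  step_dataset(c(tf, th),
               c(rep("front", n_steps), rep("hind", n_steps)),
               rep(bout, 2 * n_steps))
}

# Bivariate VAR(1)/VAR(2) simulators for causality tests.
sim_ar1 <- function(n, phi = 0.8, sd = 1) {
  x <- numeric(n)
  for (t in 2:n) x[t] <- phi * x[t - 1] + rnorm(1, 0, sd)
  x
}

# y driven by x at a given lag with given gain; x autonomous AR(1).
sim_cross_driven <- function(n, gain = 0.6, lag = 2, phi = 0.5, sd = 0.5) {
  x <- sim_ar1(n, phi = phi, sd = 1)
  y <- numeric(n)
  for (t in (lag + 1):n) y[t] <- gain * x[t - lag] + rnorm(1, 0, sd)
  list(x = x, y = y)
}

# Independent brute-force circular resultant computation (complex sum).
brute_resultant <- function(angles_deg) {
  z <- mean(exp(1i * angles_deg * pi / 180))
  list(R_bar = Mod(z), mean_angle = (Arg(z) * 180 / pi) %% 360)
}

# Watson-Williams permutation oracle: permute group labels, recompute the
# corrected F, return the upper-tail permutation p-value.
ww_permutation_p <- function(groups, n_perm = 2000) {
  f_obs <- circular_anova(groups)$F
  all_ang <- unlist(groups)
  sizes <- vapply(groups, length, integer(1))
  idx_end <- cumsum(sizes)
  idx_start <- c(1, head(idx_end, -1) + 1)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    sh <- sample(all_ang)
    g <- lapply(seq_along(sizes), function(k) sh[idx_start[k]:idx_end[k]])
    circular_anova(g)$F
  }, numeric(1))
  mean(f_perm >= f_obs)
}
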