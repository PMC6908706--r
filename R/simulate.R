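#' Parameters of the coupled two-walker stepping model
#'
#' The generative model is a linear phase-correction process of sensorimotor
#' synchronization, operating directly on event times: each walker's next
#' onset is its last onset plus the bout's period, plus per-step motor noise,
#' minus a gain times its current asynchrony to the partner's nearest onset.
#' Defaults emulate synchronized bipedal walking in chimpanzees: base tempo
#' 0.89 s, per-step motor noise 0.03 s, between-bout tempo drift 0.15 s
#' (pooled step-duration SD then ~0.15 s), mutual coupling 0.25/0.25 (the
#' asynchrony then halves every step), zero initial offset.
#'
#' @param base_period Mean step period across bouts, seconds (default 0.89).
#' @param motor_noise_sd Per-step timing noise SD, seconds (default 0.03).
#' @param drift_sd SD of the per-bout period around `base_period`, seconds
#'   (default 0.15); per-bout periods are truncated to `[0.5, 1.6]` s.
#' @param coupling_front_from_hind,coupling_hind_from_front Phase-correction
#'   gains in `[0, 1]` (defaults 0.25 each).
#' @param initial_offset Hind walker's first onset minus the front walker's,
#'   seconds (default 0).
#' @return Object of class `walker_params`.
#' @export
walker_params <- function(base_period = 0.89, motor_noise_sd = 0.03,
                          drift_sd = 0.15,
                          coupling_front_from_hind = 0.25,
                          coupling_hind_from_front = 0.25,
                          initial_offset = 0) {
  if (base_period <= 0) stop("base_period must be > 0")
  if (motor_noise_sd < 0 || drift_sd < 0) stop("noise SDs must be >= 0")
  g <- c(coupling_front_from_hind, coupling_hind_from_front)
  if (any(g < 0 | g > 1)) stop("coupling gains must lie in [0, 1]")
  structure(list(base_period = base_period, motor_noise_sd = motor_noise_sd,
                 drift_sd = drift_sd,
                 coupling_front_from_hind = coupling_front_from_hind,
                 coupling_hind_from_front = coupling_hind_from_front,
                 initial_offset = initial_offset),
            class = "walker_params")
}

#' Simulation configuration
#'
#' @param n_bouts Number of bouts to generate (default 28).
#' @param bout_duration_range Length-2 range of bout durations, seconds
#'   (default `c(2.6, 48)`); durations are drawn uniformly.
#' @param rate Sampling rate the downstream analysis will use, Hz
#'   (default 100).
#' @param seed Integer seed; every stochastic draw derives from it, so the
#'   output is fully reproducible. `NULL` uses the current RNG state.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_bouts = 28, bout_duration_range = c(2.6, 48),
                       rate = 100, seed = NULL) {
  if (n_bouts < 1) stop("n_bouts must be >= 1")
  r <- bout_duration_range
  if (length(r) != 2 || r[1] <= 0 || r[2] < r[1])
    stop("bout_duration_range must be positive and ordered")
  structure(list(n_bouts = as.integer(n_bouts), bout_duration_range = r,
                 rate = rate, seed = seed),
            class = "sim_config")
}

# Per-bout period: base + Normal(0, drift_sd), redrawn until inside
# [0.5, 1.6] s (the plausible stepping band); zero drift just clamps.
draw_bout_period <- function(base, drift_sd, lo = 0.5, hi = 1.6) {
  if (drift_sd == 0) return(min(max(base, lo), hi))
  for (i in 1:1000) {
    Tb <- base + stats::rnorm(1, 0, drift_sd)
    if (Tb >= lo && Tb <= hi) return(Tb)
  }
  min(max(base, lo), hi)  # pathological parameters; fall back to clamping
}

nearest_onset <- function(v, t) v[which.min(abs(v - t))]

# Simulate one bout of the coupled walker pair. Returns list(front, hind)
# onset vectors (seconds from bout start, >= 0, millisecond-rounded).
simulate_bout <- function(params, duration, period_front,
                          period_hind = period_front,
                          offset = params$initial_offset) {
  g_f <- params$coupling_front_from_hind
  g_h <- params$coupling_hind_from_front
  noise <- params$motor_noise_sd
  t_f <- 0; t_h <- offset
  on_f <- t_f; on_h <- t_h
  alive_f <- TRUE; alive_h <- TRUE
  min_step <- 0.1  # floor on step duration: feet cannot retouch instantly
  while (alive_f || alive_h) {
    adv_front <- alive_f && (!alive_h || t_f <= t_h)
    if (adv_front) {
      corr <- if (g_f > 0) g_f * (t_f - nearest_onset(on_h, t_f)) else 0
      nxt <- t_f + period_front + stats::rnorm(1, 0, noise) - corr
      nxt <- max(nxt, t_f + min_step)
      if (nxt > duration) alive_f <- FALSE
      else { t_f <- nxt; on_f <- c(on_f, nxt) }
    } else {
      corr <- if (g_h > 0) g_h * (t_h - nearest_onset(on_f, t_h)) else 0
      nxt <- t_h + period_hind + stats::rnorm(1, 0, noise) - corr
      nxt <- max(nxt, t_h + min_step)
      if (nxt > duration) alive_h <- FALSE
      else { t_h <- nxt; on_h <- c(on_h, nxt) }
    }
  }
  shift <- min(on_f[1], on_h[1])
  list(front = round(on_f - shift, 3), hind = round(on_h - shift, 3))
}

bout_rows <- function(bout_id, onsets) {
  data.frame(time = c(onsets$front, onsets$hind),
             subject = c(rep("front", length(onsets$front)),
                         rep("hind", length(onsets$hind))),
             bout = bout_id, stringsAsFactors = FALSE)
}

#' Simulate a coupled two-walker dataset
#'
#' Generates `n_bouts` bouts of dyadic stepping under the linear
#' phase-correction model (see [walker_params()]). Both walkers share the
#' bout's period; with simultaneous updates the asynchrony follows
#' `d_next = (1 - g_front - g_hind) * d` plus noise, so symmetric gains of
#' 0.25 halve it every step. Onset times are rounded to milliseconds, which
#' makes the dataset serialize exactly through [write_step_events()].
#'
#' @param params A [walker_params()].
#' @param config A [sim_config()].
#' @return A [step_dataset()] with bouts `"bout01"`, `"bout02"`, ...; the
#'   realized per-bout generative periods are attached as the `sim_periods`
#'   attribute for parameter-recovery studies.
#' @examples
#' d <- simulate_dyad(walker_params(), sim_config(n_bouts = 3, seed = 1))
#' bout_durations(d)
#' @export
simulate_dyad <- function(params = walker_params(), config = sim_config()) {
  stopifnot(inherits(params, "walker_params"), inherits(config, "sim_config"))
  run <- function() {
    rows <- vector("list", config$n_bouts)
    periods <- numeric(config$n_bouts)
    for (i in seq_len(config$n_bouts)) {
      dur <- stats::runif(1, config$bout_duration_range[1],
                          config$bout_duration_range[2])
      Tb <- draw_bout_period(params$base_period, params$drift_sd)
      periods[i] <- Tb
      rows[[i]] <- bout_rows(sprintf("bout%02d", i),
                             simulate_bout(params, dur, Tb))
    }
    list(rows = do.call(rbind, rows), periods = periods)
  }
  r <- if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
  d <- step_dataset(r$rows$time, r$rows$subject, r$rows$bout,
                    provenance = sprintf("simulate_dyad(seed = %s)",
                                         config$seed %||% "NULL"))
  # realized per-bout generative periods, for parameter-recovery studies
  attr(d, "sim_periods") <- stats::setNames(r$periods,
                                            sprintf("bout%02d",
                                                    seq_len(config$n_bouts)))
  d
}

#' Simulate an uncoupled (null) two-walker dataset
#'
#' Both walkers step with zero coupling, independent per-bout periods, and an
#' independent random initial phase for the hind walker (uniform over one
#' hind period). Used for type-I calibration of the Rayleigh and Granger
#' stages: under this null, neither walker's past carries information about
#' the other's timing.
#'
#' @param config A [sim_config()].
#' @param params A [walker_params()]; coupling gains are ignored (forced
#'   to 0).
#' @return A [step_dataset()].
#' @export
null_dataset <- function(config = sim_config(), params = walker_params()) {
  stopifnot(inherits(params, "walker_params"), inherits(config, "sim_config"))
  p0 <- params
  p0$coupling_front_from_hind <- 0
  p0$coupling_hind_from_front <- 0
  run <- function() {
    rows <- vector("list", config$n_bouts)
    for (i in seq_len(config$n_bouts)) {
      dur <- stats::runif(1, config$bout_duration_range[1],
                          config$bout_duration_range[2])
      T_f <- draw_bout_period(p0$base_period, p0$drift_sd)
      T_h <- draw_bout_period(p0$base_period, p0$drift_sd)
      off <- stats::runif(1, 0, T_h)
      rows[[i]] <- bout_rows(sprintf("bout%02d", i),
                             simulate_bout(p0, dur, T_f, T_h, offset = off))
    }
    do.call(rbind, rows)
  }
  d <- if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
  step_dataset(d$time, d$subject, d$bout,
               provenance = sprintf("null_dataset(seed = %s)",
                                    config$seed %||% "NULL"))
}
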