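deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# circular mean direction in radians of angles given in radians
circ_mean_rad <- function(a) atan2(mean(sin(a)), mean(cos(a)))

#' Map step onsets to phase angles on a reference period
#'
#' Expresses each onset as an angle on the circle defined by a reference
#' period T (360 degrees = one period), anchored so that `t0` (by default the
#' first onset) maps exactly to 0 degrees:
#' `angle_i = 360 * (((onset_i - t0) mod T) / T)`.
#' Adding any integer multiple of T to all onsets leaves the angles
#' unchanged.
#'
#' @param onsets Non-empty numeric vector of onset times, seconds.
#' @param period Reference period T in seconds (> 0).
#' @param t0 Anchor time mapped to 0 degrees; defaults to the first onset.
#' @param subject,bout Optional labels carried along for bookkeeping.
#' @return An object of class `phase_angles`: numeric vector of angles in
#'   `[0, 360)` with attributes `period`, `t0`, `subject`, `bout`.
#' @examples
#' to_phase_angles(c(0, 0.89, 1.78), period = 0.89)  # all 0
#' @export
to_phase_angles <- function(onsets, period, t0 = NULL, subject = NULL,
                            bout = NULL) {
  if (!is.numeric(period) || period <= 0) stop("period must be > 0")
  onsets <- as.numeric(onsets)
  if (length(onsets) == 0) stop("onsets must be non-empty")
  t0 <- t0 %||% onsets[1]
  ang <- 360 * (((onsets - t0) %% period) / period)
  ang[ang >= 360] <- 0  # guard against rounding at the wrap point
  structure(ang, period = period, t0 = t0, subject = subject, bout = bout,
            class = "phase_angles")
}

#' @export
print.phase_angles <- function(x, ...) {
  cat(sprintf("<phase_angles> n = %d on period %.4g s\n",
              length(x), attr(x, "period")))
  print(as.numeric(x))
  invisible(x)
}

#' Rayleigh test p-value from the mean resultant length
#'
#' Large-sample approximation for the Rayleigh test of circular uniformity:
#' with `R = n * R_bar`, `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))`.
#'
#' @param r_bar Mean resultant length in `[0, 1]`.
#' @param n Sample size.
#' @return p-value in `(0, 1]`.
#' @export
rayleigh_p <- function(r_bar, n) {
  R <- n * r_bar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  min(max(p, .Machine$double.xmin), 1)
}

#' Circular summary statistics of a sample of phase angles
#'
#' Mean direction, mean resultant length, circular standard deviation
#' (`sqrt(-2 log R_bar)`, reported in degrees) and the Rayleigh uniformity
#' test.
#'
#' @param angles A [to_phase_angles()] result or numeric vector of angles in
#'   degrees (at least 2).
#' @return Object of class `circular_summary`: list with `n`, `mean_angle`
#'   (degrees in `[0, 360)`), `R_bar`, `circ_sd` (degrees; `Inf` when
#'   `R_bar = 0`), `rayleigh_p`.
#' @export
circular_summary <- function(angles) {
  a <- as.numeric(angles)
  if (length(a) < 2) stop("need at least 2 angles")
  ar <- deg2rad(a)
  C <- mean(cos(ar)); S <- mean(sin(ar))
  r_bar <- min(sqrt(C^2 + S^2), 1)
  mean_angle <- rad2deg(atan2(S, C)) %% 360
  circ_sd <- if (r_bar > 0) rad2deg(sqrt(-2 * log(r_bar))) else Inf
  structure(list(n = length(a), mean_angle = mean_angle, R_bar = r_bar,
                 circ_sd = circ_sd, rayleigh_p = rayleigh_p(r_bar, length(a))),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf(
    "<circular_summary> n = %d, mean = %.2f deg, R_bar = %.3f, circ SD = %.2f deg, Rayleigh p = %.3g\n",
    x$n, x$mean_angle, x$R_bar, x$circ_sd, x$rayleigh_p))
  invisible(x)
}

# Fisher's approximation to the von Mises concentration MLE from a mean
# resultant length r.
kappa_from_rbar <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams circular analysis of variance
#'
#' High-concentration F test for equality of mean directions across groups,
#' with the standard correction factor `1 + 3 / (8 kappa_hat)` where
#' `kappa_hat` is estimated from the within-group mean resultant length. The
#' test assumes concentrated von Mises samples; when any group's mean
#' resultant length falls below 0.45 the result carries a
#' `low_concentration` flag (the F approximation degrades there) but is
#' still returned.
#'
#' @param groups List of two or more angle vectors (degrees), each with at
#'   least 2 angles.
#' @return Object of class `circ_anova`: list with `F` (corrected
#'   statistic), `df_between`, `df_within`, `p`, `kappa_hat`,
#'   `low_concentration`.
#' @export
circular_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs >= 2 angles")
  rads <- lapply(groups, function(g) deg2rad(as.numeric(g)))
  ns <- vapply(rads, length, integer(1))
  N <- sum(ns); k <- length(rads)
  # per-group and pooled resultant lengths (not normalized)
  Ri <- vapply(rads, function(a) sqrt(sum(cos(a))^2 + sum(sin(a))^2),
               numeric(1))
  Call <- sum(vapply(rads, function(a) sum(cos(a)), numeric(1)))
  Sall <- sum(vapply(rads, function(a) sum(sin(a)), numeric(1)))
  R <- sqrt(Call^2 + Sall^2)
  rw <- sum(Ri) / N
  kap <- kappa_from_rbar(min(rw, 0.999999))
  num <- sum(Ri) - R
  den <- N - sum(Ri)
  if (den < 1e-12 * N) {
    # perfectly concentrated groups: zero within-group dispersion
    Fc <- if (num < 1e-12 * N) 0 else Inf
  } else {
    Fstat <- ((N - k) * num) / ((k - 1) * den)
    Fc <- max(Fstat * (1 + 3 / (8 * kap)), 0)
  }
  structure(list(F = Fc, df_between = k - 1L, df_within = N - k,
                 p = stats::pf(Fc, k - 1, N - k, lower.tail = FALSE),
                 kappa_hat = kap,
                 low_concentration = any(Ri / ns < 0.45)),
            class = "circ_anova")
}

#' @export
print.circ_anova <- function(x, ...) {
  cat(sprintf("<circ_anova> F(%d, %d) = %.4g, p = %.3g, kappa_hat = %.3g%s\n",
              x$df_between, x$df_within, x$F, x$p, x$kappa_hat,
              if (x$low_concentration) " [low concentration]" else ""))
  invisible(x)
}

# Jammalamadaka-Sarma circular correlation coefficient of paired angles in
# radians; NA when either sample has zero angular deviation.
r_js_rad <- function(a, b) {
  sa <- sin(a - circ_mean_rad(a))
  sb <- sin(b - circ_mean_rad(b))
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(NA_real_)
  sum(sa * sb) / den
}

#' Jammalamadaka-Sarma circular correlation with bootstrap interval
#'
#' Correlation of two paired circular samples:
#' `r_JS = sum sin(a_i - a_mean) sin(b_i - b_mean) / sqrt(sum sin^2(...) *
#' sum sin^2(...))` with circular means. The p-value uses the standard
#' asymptotic normal approximation; the 95% confidence interval is a
#' percentile bootstrap over paired resamples with a fixed seed.
#' Samples are paired by index and truncated to the common length.
#'
#' @param a,b Angle vectors in degrees (paired; common length >= 3 after
#'   truncation).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap (default 20191212); the caller's RNG
#'   state is untouched.
#' @return Object of class `circ_corr`: list with `r_js`, `p`, `ci95`
#'   (length-2), `n`, `n_boot`, `seed`.
#' @export
circular_correlation <- function(a, b, n_boot = 1000, seed = 20191212) {
  m <- min(length(a), length(b))
  if (m < 3) stop("need at least 3 paired angles")
  ar <- deg2rad(as.numeric(a)[1:m])
  br <- deg2rad(as.numeric(b)[1:m])
  r <- r_js_rad(ar, br)
  # asymptotic null variance (Jammalamadaka & SenGupta)
  sa <- sin(ar - circ_mean_rad(ar)); sb <- sin(br - circ_mean_rad(br))
  l20 <- mean(sa^2); l02 <- mean(sb^2); l22 <- mean(sa^2 * sb^2)
  p <- if (!is.na(r) && l22 > 0) {
    z <- sqrt(m * l20 * l02 / l22) * r
    2 * stats::pnorm(-abs(z))
  } else NA_real_
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(m, m, replace = TRUE)
      r_js_rad(ar[idx], br[idx])
    }, numeric(1))
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  structure(list(r_js = r, p = p, ci95 = ci, n = m,
                 n_boot = n_boot, seed = seed),
            class = "circ_corr")
}

#' @export
print.circ_corr <- function(x, ...) {
  cat(sprintf("<circ_corr> r_JS = %.3f, p = %.3g, CI95 = [%.3f, %.3f] (n = %d, %d resamples)\n",
              x$r_js, x$p, x$ci95[1], x$ci95[2], x$n, x$n_boot))
  invisible(x)
}

#' Export phase angles as a long table
#' @param angle_list List of [to_phase_angles()] objects.
#' @param path Optional TSV path; if `NULL` the data frame is returned.
#' @return Data frame with columns `bout`, `subject`, `step_index`,
#'   `angle_deg`.
#' @export
angles_table <- function(angle_list, path = NULL) {
  rows <- lapply(angle_list, function(a) {
    data.frame(bout = attr(a, "bout") %||% NA_character_,
               subject = attr(a, "subject") %||% NA_character_,
               step_index = seq_along(a), angle_deg = as.numeric(a))
  })
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
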