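# Extract the sample vector from a pulse_series or plain numeric input.
series_values <- function(x) {
  if (inherits(x, "pulse_series")) x$values else as.numeric(x)
}

series_rate <- function(x, rate = NULL) {
  if (inherits(x, "pulse_series")) x$rate
  else rate %||% stop("rate must be supplied for plain numeric series")
}

# Design matrix for a bivariate VAR(p): intercept plus lags 1..p of x and of
# y, with responses starting at row `offset + 1` (offset >= p). Using a
# common offset lets models of different order be compared on the same
# estimation sample.
var_design <- function(x, y, p, offset = p) {
  n <- length(x)
  if (offset < p) stop("offset must be >= p")
  rows <- (offset + 1):n
  X <- matrix(1, nrow = length(rows), ncol = 1 + 2 * p)
  for (j in seq_len(p)) {
    X[, 1 + j] <- x[rows - j]
    X[, 1 + p + j] <- y[rows - j]
  }
  colnames(X) <- c("const", paste0("x.l", seq_len(p)), paste0("y.l", seq_len(p)))
  list(X = X, Y = cbind(x = x[rows], y = y[rows]))
}

# OLS via QR; errors on rank deficiency (degenerate, e.g. constant series).
ols_fit <- function(X, Y) {
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X))
    stop("degenerate design (rank deficient); constant or collinear series")
  B <- qr.coef(qr_X, Y)
  res <- Y - X %*% B
  list(coef = B, residuals = res, rss = colSums(res^2))
}

#' Fit a bivariate vector autoregression by equation-wise OLS
#'
#' Fits `VAR(p)` to two equally sampled series: each variable is regressed on
#' an intercept and lags `1..p` of both variables. Coefficients satisfy the
#' normal equations (residuals orthogonal to regressors).
#'
#' @param a,b [pulse_series()] objects (or numeric vectors) of equal length
#'   `n > 4p + 2`.
#' @param p Lag order in samples (>= 1).
#' @param offset Number of initial samples reserved for lags (default `p`);
#'   pass a larger value to estimate on a common sample across orders.
#' @return Object of class `var_fit`: list with `coef` ((2p+1) x 2 matrix),
#'   `residuals`, `rss` (per equation), `sigma` (residual covariance, MLE),
#'   `logdet_sigma`, `n_eff`, `p`, `aic`
#'   (`log det(Sigma) + 2 * (4p + 2) / n_eff`).
#' @export
fit_var <- function(a, b, p, offset = p) {
  x <- series_values(a); y <- series_values(b)
  if (length(x) != length(y)) stop("series lengths differ")
  if (p < 1) stop("p must be >= 1")
  if (length(x) <= 4 * p + 2)
    stop("series too short for VAR(", p, "): need n > ", 4 * p + 2)
  d <- var_design(x, y, p, offset)
  f <- ols_fit(d$X, d$Y)
  n_eff <- nrow(d$X)
  Sigma <- crossprod(f$residuals) / n_eff
  ld <- determinant(Sigma, logarithm = TRUE)
  logdet <- if (ld$sign > 0) as.numeric(ld$modulus) else -Inf
  structure(list(coef = f$coef, residuals = f$residuals, rss = f$rss,
                 sigma = Sigma, logdet_sigma = logdet, n_eff = n_eff, p = p,
                 aic = logdet + 2 * (4 * p + 2) / n_eff),
            class = "var_fit")
}

#' @export
print.var_fit <- function(x, ...) {
  cat(sprintf("<var_fit> VAR(%d), n_eff = %d, AIC = %.4f\n",
              x$p, x$n_eff, x$aic))
  print(round(x$coef, 4))
  invisible(x)
}

#' Select the VAR lag order by information criterion
#'
#' Evaluates `VAR(p)` for every `p` on a grid of lags from one sample up to
#' `max_lag` seconds, all fitted on the common estimation sample implied by
#' the largest candidate, and returns the AIC-minimizing lag (ties broken
#' toward the smaller order).
#'
#' @param a,b Series as in [fit_var()].
#' @param max_lag Largest candidate lag, seconds (default 0.3).
#' @param rate Sampling rate in Hz; taken from `a` when it is a
#'   [pulse_series()].
#' @return Object of class `lag_selection`: list with `candidate_lags`
#'   (seconds), `aic` (per candidate), `optimal_lag` (seconds), `optimal_p`
#'   (samples), `truncated` (TRUE when the series could not support the full
#'   grid, with a warning).
#' @export
select_var_lag <- function(a, b, max_lag = 0.3, rate = NULL) {
  rate <- series_rate(a, rate)
  x <- series_values(a); y <- series_values(b)
  p_max <- as.integer(floor(max_lag * rate + 1e-9))
  if (p_max < 1) stop("max_lag shorter than one sample")
  truncated <- FALSE
  p_feas <- as.integer(floor((length(x) - 3) / 5))  # n - p > 4p + 2
  if (p_feas < 1) stop("series too short for any VAR order")
  if (p_feas < p_max) {
    warning("series supports only lags up to ", p_feas, " samples; grid truncated")
    p_max <- p_feas
    truncated <- TRUE
  }
  aics <- vapply(seq_len(p_max),
                 function(p) fit_var(x, y, p, offset = p_max)$aic, numeric(1))
  best <- which(aics <= min(aics) + 1e-12)[1]
  structure(list(candidate_lags = seq_len(p_max) / rate, aic = aics,
                 optimal_lag = best / rate, optimal_p = as.integer(best),
                 truncated = truncated),
            class = "lag_selection")
}

#' @export
print.lag_selection <- function(x, ...) {
  cat(sprintf("<lag_selection> optimal lag %.3f s (p = %d of %d candidates)%s\n",
              x$optimal_lag, x$optimal_p, length(x$candidate_lags),
              if (x$truncated) " [grid truncated]" else ""))
  invisible(x)
}

# One-directional Granger F test: does x's past improve prediction of y
# beyond y's own past? Restricted and full models share the estimation
# sample. Returns F, p, and the residual dfs.
granger_f <- function(x, y, p) {
  d <- var_design(x, y, p)
  n_eff <- nrow(d$X)
  yy <- d$Y[, 2]
  own <- c(1, (2 + p):(1 + 2 * p))   # intercept + y lags
  full <- ols_fit(d$X, cbind(yy))
  restr <- ols_fit(d$X[, own, drop = FALSE], cbind(yy))
  df2 <- n_eff - (2 * p + 1)
  Fstat <- ((restr$rss - full$rss) / p) / (full$rss / df2)
  list(F = unname(Fstat), p = unname(stats::pf(Fstat, p, df2, lower.tail = FALSE)),
       df1 = p, df2 = df2)
}

#' Per-bout leadership classification by Granger causality
#'
#' Tests, in both directions, whether one subject's past improves the
#' prediction of the other's series beyond its own past (F test of joint
#' nullity of the cross-lag coefficients, restricted vs full OLS), and
#' classifies the bout: `front_leads`, `hind_leads`, `bidirectional`
#' (both directions significant), or `none`. Degenerate fits (constant or
#' collinear series) yield classification `none` with `degenerate = TRUE`.
#'
#' @param front,hind The two subjects' (smoothed) [pulse_series()] for one
#'   bout, or numeric vectors with `rate` supplied.
#' @param lag Lag in seconds (converted to samples; >= 1 sample).
#' @param alpha Significance level per direction (default 0.05; no
#'   multiple-testing correction across bouts, mirroring common practice in
#'   dyadic synchrony analyses).
#' @param rate Sampling rate in Hz if the inputs are plain vectors.
#' @param bout_id Optional identifier carried into the result.
#' @return Object of class `granger_result`: list with `bout_id`,
#'   `p_front_to_hind`, `p_hind_to_front`, `stat_f2h`, `stat_h2f`,
#'   `lag_used` (seconds), `p_samples`, `classification`, `degenerate`.
#' @export
granger_classify <- function(front, hind, lag, alpha = 0.05, rate = NULL,
                             bout_id = NULL) {
  rate <- series_rate(front, rate)
  x <- series_values(front); y <- series_values(hind)
  if (length(x) != length(y)) stop("series lengths differ")
  p <- max(1L, as.integer(round(lag * rate)))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  out <- list(bout_id = bout_id, lag_used = p / rate, p_samples = p,
              degenerate = FALSE)
  res <- tryCatch(list(f2h = granger_f(x, y, p), h2f = granger_f(y, x, p)),
                  error = function(e) NULL)
  if (is.null(res) || !is.finite(res$f2h$F) || !is.finite(res$h2f$F)) {
    out$p_front_to_hind <- NA_real_; out$p_hind_to_front <- NA_real_
    out$stat_f2h <- NA_real_; out$stat_h2f <- NA_real_
    out$classification <- "none"; out$degenerate <- TRUE
  } else {
    out$p_front_to_hind <- res$f2h$p; out$p_hind_to_front <- res$h2f$p
    out$stat_f2h <- res$f2h$F; out$stat_h2f <- res$h2f$F
    sig_f <- res$f2h$p < alpha; sig_h <- res$h2f$p < alpha
    out$classification <- if (sig_f && sig_h) "bidirectional"
      else if (sig_f) "front_leads"
      else if (sig_h) "hind_leads"
      else "none"
  }
  structure(out, class = "granger_result")
}

# One direction of the phase-correction Granger test: does the driver's
# relative timing (step asynchrony) predict the responder's next inter-step
# interval beyond the responder's own interval history?
# resp_t, driver_t: paired onset times (length m). Returns F plus the
# restricted AR fit needed by the bootstrap.
pc_design <- function(resp_I, asyn, p) {
  jmax <- length(resp_I)
  rows <- (p + 1):jmax
  X_own <- matrix(1, length(rows), 1 + p)
  for (l in seq_len(p)) X_own[, 1 + l] <- resp_I[rows - l]
  X_cross <- matrix(0, length(rows), p)
  for (l in seq_len(p)) X_cross[, l] <- asyn[rows - l + 1]
  list(y = resp_I[rows], X_r = X_own, X_f = cbind(X_own, X_cross),
       n_eff = length(rows))
}

# statistic = "F" (two-sided, joint nullity of the asynchrony terms) or
# "t" (signed t of the summed asynchrony coefficients; positive = corrective
# coupling toward the driver).
pc_fstat <- function(resp_I, asyn, p, statistic = "F") {
  d <- pc_design(resp_I, asyn, p)
  restr <- ols_fit(d$X_r, cbind(d$y))
  full <- ols_fit(d$X_f, cbind(d$y))
  df2 <- d$n_eff - ncol(d$X_f)
  Fst <- unname(((restr$rss - full$rss) / p) / (full$rss / df2))
  out <- list(F = Fst, df1 = p, df2 = df2, restr = restr)
  if (statistic == "t") {
    s2 <- full$rss / df2
    XtXi <- chol2inv(chol(crossprod(d$X_f)))
    cross_ix <- (ncol(d$X_f) - p + 1):ncol(d$X_f)
    gsum <- sum(full$coef[cross_ix, 1])
    se <- sqrt(s2 * sum(XtXi[cross_ix, cross_ix]))
    out$stat <- gsum / se
  } else out$stat <- Fst
  out
}

# Residual bootstrap p-value: rebuild the responder's intervals recursively
# from the restricted (own-history-only) AR fit with resampled centred
# residuals, recompute the asynchrony against the fixed driver onsets, and
# take the exceedance probability of the recomputed F.
pc_boot_p <- function(resp_t, driver_t, p, n_boot, statistic = "t") {
  m <- length(resp_t)
  resp_I <- diff(resp_t)
  asyn <- driver_t - resp_t
  obs <- pc_fstat(resp_I, asyn, p, statistic)
  if (!is.finite(obs$stat)) return(list(F = obs$F, p = NA_real_))
  if (n_boot < 1) {
    p_asym <- if (statistic == "t")
      stats::pt(obs$stat, obs$df2, lower.tail = FALSE)
    else stats::pf(obs$F, obs$df1, obs$df2, lower.tail = FALSE)
    return(list(F = obs$F, p = p_asym))
  }
  coefs <- obs$restr$coef[, 1]
  res <- obs$restr$residuals[, 1]
  res <- res - mean(res)
  nI <- length(resp_I)
  exceed <- 0L
  for (b in seq_len(n_boot)) {
    e <- sample(res, nI, replace = TRUE)
    I_b <- resp_I
    for (j in (p + 1):nI)
      I_b[j] <- coefs[1] + sum(coefs[-1] * I_b[j - seq_len(p)]) + e[j]
    t_b <- cumsum(c(resp_t[1], I_b))
    s_b <- pc_fstat(I_b, driver_t - t_b, p, statistic)$stat
    if (is.finite(s_b) && s_b >= obs$stat) exceed <- exceed + 1L
  }
  list(F = obs$F, p = (1 + exceed) / (n_boot + 1))
}

#' Leadership inference from paired step onsets (phase-correction Granger)
#'
#' Event-domain Granger test built on the linear phase-correction model of
#' sensorimotor synchronization: for each walker, the next inter-step
#' interval is regressed on the walker's own interval history (lags `1..p`)
#' plus lagged step asynchronies to the partner; the partner "Granger-leads"
#' when the asynchrony terms jointly improve prediction (restricted vs full
#' OLS F). Because the asynchrony integrates the responder's own past, the
#' F statistic is not F-distributed under the null; the p-value therefore
#' comes from a recursive residual bootstrap under the restricted model
#' (`n_boot = 0` falls back to the asymptotic F approximation).
#'
#' @param front_onsets,hind_onsets Onset times (seconds) of the two subjects
#'   in one bout; paired by step index and truncated to the common length.
#' @param p Number of interval/asynchrony lags (default 1, the standard
#'   first-order phase-correction model).
#' @param alpha Significance level per direction (default 0.05).
#' @param n_boot Bootstrap replicates (default 199).
#' @param seed Optional seed for the bootstrap (caller's RNG untouched).
#' @param alternative `"corrective"` (default) tests the one-sided
#'   hypothesis of positive phase correction toward the partner — the
#'   scientifically relevant alternative for entrainment — via the signed t
#'   of the summed asynchrony coefficients; `"two.sided"` uses the joint F.
#' @param bout_id Optional identifier carried into the result.
#' @return A `granger_result` (same shape as [granger_classify()]) with
#'   `lag_used` expressed in steps.
#' @export
granger_events <- function(front_onsets, hind_onsets, p = 1, alpha = 0.05,
                           n_boot = 199, seed = NULL,
                           alternative = c("corrective", "two.sided"),
                           bout_id = NULL) {
  if (p < 1) stop("p must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stat <- if (match.arg(alternative) == "corrective") "t" else "F"
  m <- min(length(front_onsets), length(hind_onsets))
  out <- list(bout_id = bout_id, lag_used = p, p_samples = p,
              degenerate = FALSE)
  run <- function() {
    tf <- front_onsets[1:m]; th <- hind_onsets[1:m]
    f2h <- tryCatch(pc_boot_p(th, tf, p, n_boot, stat),
                    error = function(e) NULL)
    h2f <- tryCatch(pc_boot_p(tf, th, p, n_boot, stat),
                    error = function(e) NULL)
    list(f2h = f2h, h2f = h2f)
  }
  # degrees of freedom require a few more steps than parameters
  if (m - 1 - p < 2 * p + 1 + 3) {
    out$p_front_to_hind <- NA_real_; out$p_hind_to_front <- NA_real_
    out$stat_f2h <- NA_real_; out$stat_h2f <- NA_real_
    out$classification <- "none"; out$degenerate <- TRUE
    return(structure(out, class = "granger_result"))
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  bad <- function(r) is.null(r) || !is.finite(r$F) || is.na(r$p)
  if (bad(res$f2h) || bad(res$h2f)) {
    out$p_front_to_hind <- NA_real_; out$p_hind_to_front <- NA_real_
    out$stat_f2h <- NA_real_; out$stat_h2f <- NA_real_
    out$classification <- "none"; out$degenerate <- TRUE
  } else {
    out$p_front_to_hind <- res$f2h$p; out$p_hind_to_front <- res$h2f$p
    out$stat_f2h <- res$f2h$F; out$stat_h2f <- res$h2f$F
    sig_f <- res$f2h$p < alpha; sig_h <- res$h2f$p < alpha
    out$classification <- if (sig_f && sig_h) "bidirectional"
      else if (sig_f) "front_leads"
      else if (sig_h) "hind_leads"
      else "none"
  }
  structure(out, class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf(
    "<granger_result>%s lag %.2f s: F->H p = %.3g, H->F p = %.3g => %s%s\n",
    if (is.null(x$bout_id)) "" else paste0(" [", x$bout_id, "]"),
    x$lag_used, x$p_front_to_hind, x$p_hind_to_front, x$classification,
    if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}
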