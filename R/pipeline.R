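#' Analysis configuration
#'
#' Bundles every tunable of the analysis pipeline with its default.
#'
#' @param rate_hz Sampling rate for pulse series (default 100).
#' @param filter_order Butterworth order (default 3).
#' @param filter_cutoff_hz Low-pass cutoff, Hz (default 4).
#' @param ac_window_s Autocorrelation search window, seconds
#'   (default `c(0.5, 1.5)`).
#' @param xc_range_s Cross-correlation maximum |lag|, seconds (default 0.5).
#' @param xc_increment_s Cross-correlation lag grid spacing, seconds
#'   (default 1/24).
#' @param granger_domain Where the leadership test runs: `"event"` (default)
#'   applies the phase-correction Granger test [granger_events()] to the
#'   paired step onsets (bootstrap-calibrated, matched to the event-based
#'   observable); `"series"` fits a bivariate VAR to the smoothed 100 Hz
#'   pulse series with an AIC-selected lag, mirroring the classical
#'   sampled-series procedure (note its F test is anticonservative there;
#'   see the package vignette).
#' @param granger_event_lag Interval/asynchrony lag order for the event
#'   domain (default 1).
#' @param granger_n_boot Bootstrap replicates per direction for the event
#'   domain (default 199).
#' @param granger_max_lag_s Largest candidate VAR lag in seconds for the
#'   series domain (default 0.3).
#' @param alpha Per-direction Granger significance level (default 0.05).
#' @param p_adjust Multiple-testing adjustment for the per-bout Granger
#'   p-values: `"none"` (default) or `"BH"`.
#' @param n_boot Bootstrap resamples for the circular correlation
#'   (default 1000).
#' @param seed Seed for all stochastic steps (default 20191212).
#' @param reference_tempi Named vector of reference step tempi (seconds) for
#'   one-sample comparisons; defaults to published bipedal gait tempi for
#'   the genus: 0.81 s (wild) and 1.21 s (captive).
#' @param per_bout_period If `TRUE`, phase angles use each bout's own
#'   autocorrelation period instead of the global one (default `FALSE`).
#' @param angle_basis What is expressed as an angle on the reference period:
#'   `"interval"` (default) maps each inter-step interval, so the angle
#'   measures tempo consistency (an interval equal to the reference period is
#'   0 degrees) and is robust to slow tempo drift; `"onset"` maps each onset
#'   time relative to the subject's first step, measuring phase locking to a
#'   strict isochronous grid (tempo drift accumulates and wraps the angle).
#' @return Object of class `entrain_config` (a named list).
#' @export
entrain_config <- function(rate_hz = 100, filter_order = 3,
                           filter_cutoff_hz = 4, ac_window_s = c(0.5, 1.5),
                           xc_range_s = 0.5, xc_increment_s = 1 / 24,
                           granger_domain = c("event", "series"),
                           granger_event_lag = 1, granger_n_boot = 199,
                           granger_max_lag_s = 0.3, alpha = 0.05,
                           p_adjust = c("none", "BH"), n_boot = 1000,
                           seed = 20191212,
                           reference_tempi = c(wild = 0.81, captive = 1.21),
                           per_bout_period = FALSE,
                           angle_basis = c("interval", "onset")) {
  structure(list(rate_hz = rate_hz, filter_order = filter_order,
                 filter_cutoff_hz = filter_cutoff_hz,
                 ac_window_s = ac_window_s, xc_range_s = xc_range_s,
                 xc_increment_s = xc_increment_s,
                 granger_domain = match.arg(granger_domain),
                 granger_event_lag = granger_event_lag,
                 granger_n_boot = granger_n_boot,
                 granger_max_lag_s = granger_max_lag_s, alpha = alpha,
                 p_adjust = match.arg(p_adjust), n_boot = n_boot, seed = seed,
                 reference_tempi = reference_tempi,
                 per_bout_period = per_bout_period,
                 angle_basis = match.arg(angle_basis)),
            class = "entrain_config")
}

#' One-sample comparison of step durations against a reference tempo
#'
#' Plain one-sample t test of observed step durations against a reference
#' mean. Sign convention: positive t means the sample is slower (longer
#' step duration) than the reference.
#'
#' @param durations Numeric vector of step durations, seconds (>= 2).
#' @param reference_mean Reference tempo, seconds (> 0).
#' @param label Optional label for the reference.
#' @return List with `label`, `reference_mean`, `mean`, `t`, `df`, `p`,
#'   `direction` (`"slower"`, `"faster"`, or `"equal"`).
#' @export
compare_tempo <- function(durations, reference_mean, label = NULL) {
  durations <- as.numeric(durations)
  if (length(durations) < 2) stop("need >= 2 durations")
  if (reference_mean <= 0) stop("reference_mean must be > 0")
  m <- mean(durations); s <- stats::sd(durations); n <- length(durations)
  if (s == 0) {
    if (m == reference_mean)
      return(list(label = label, reference_mean = reference_mean, mean = m,
                  t = 0, df = n - 1L, p = 1, direction = "equal"))
    stop("zero variance in durations")
  }
  tval <- (m - reference_mean) / (s / sqrt(n))
  list(label = label, reference_mean = reference_mean, mean = m, t = tval,
       df = n - 1L, p = 2 * stats::pt(-abs(tval), n - 1),
       direction = if (tval > 0) "slower" else if (tval < 0) "faster" else "equal")
}

csum_or_na <- function(a) {
  if (length(a) >= 2) circular_summary(a)
  else list(n = length(a), mean_angle = NA_real_, R_bar = NA_real_,
            circ_sd = NA_real_, rayleigh_p = NA_real_)
}

# Per-bout heavy lifting shared by analyze_dataset: series, smoothing,
# autocorrelation (native-lag profile on the window grid), cross-correlation.
analyze_bout <- function(of, oh, cfg) {
  span <- range(c(of, oh))
  sf <- smooth_series(events_to_series(of, cfg$rate_hz, span),
                      cfg$filter_order, cfg$filter_cutoff_hz)
  sh <- smooth_series(events_to_series(oh, cfg$rate_hz, span),
                      cfg$filter_order, cfg$filter_cutoff_hz)
  dur <- span[2] - span[1]
  ac_f <- ac_h <- NULL
  if (floor(cfg$ac_window_s[2] * cfg$rate_hz) < length(sf$values) - 3) {
    ac_f <- autocorrelation_period(sf, cfg$ac_window_s)
    ac_h <- autocorrelation_period(sh, cfg$ac_window_s)
  }
  xc <- NULL
  if (floor(cfg$xc_range_s * cfg$rate_hz) < length(sf$values) - 3)
    xc <- cross_correlation_lag(sf, sh, cfg$xc_range_s, cfg$xc_increment_s)
  list(span = span, duration = dur, series_front = sf, series_hind = sh,
       ac_front = ac_f, ac_hind = ac_h, xc = xc)
}

#' Run the full entrainment analysis on a step-onset dataset
#'
#' Per bout: builds 100 Hz pulse series for both subjects over the bout's
#' common span, smooths them, and estimates the stepping period
#' (autocorrelation) and between-subject lag (cross-correlation). Pooling
#' the per-bout autocorrelation profiles gives the global reference period;
#' onsets are then mapped to phase angles on that period (anchor: each
#' subject's first step per bout), feeding the Rayleigh, Watson-Williams
#' (between subjects and between bouts) and Jammalamadaka-Sarma statistics.
#' Finally a single AIC-selected VAR lag (summed across bouts that support
#' the full lag grid) drives the per-bout Granger leadership classification.
#' Bouts with fewer than 2 steps per subject are excluded and listed.
#'
#' The result is deterministic given the dataset, configuration, and the
#' configuration's seed.
#'
#' @param dataset A [step_dataset()].
#' @param config An [entrain_config()].
#' @return Object of class `entrain_report`: list with `bouts` (per-bout
#'   summary data frame), `aggregate` (named list of pooled statistics,
#'   circular tests and Granger counts), `angles` (list of
#'   [to_phase_angles()] per bout and subject), `granger` (per-bout
#'   [granger_classify()] results), `excluded_bouts`, `config`.
#' @export
analyze_dataset <- function(dataset, config = entrain_config()) {
  stopifnot(inherits(dataset, "step_dataset"))
  cfg <- config
  ids <- sort(bout_ids(dataset))  # canonical order: invariant to input order
  usable <- character(); excluded <- character()
  onsets <- list()
  for (b in ids) {
    of <- bout_onsets(dataset, b, "front"); oh <- bout_onsets(dataset, b, "hind")
    if (length(of) >= 2 && length(oh) >= 2) {
      usable <- c(usable, b); onsets[[b]] <- list(front = of, hind = oh)
    } else excluded <- c(excluded, b)
  }
  if (length(usable) == 0) stop("no bout has >= 2 onsets per subject")

  per <- lapply(usable, function(b)
    analyze_bout(onsets[[b]]$front, onsets[[b]]$hind, cfg))
  names(per) <- usable

  # global reference period: mean of per-bout-and-subject normalized
  # autocorrelation profiles on the common window lag grid
  k_grid <- max(1L, as.integer(ceiling(cfg$ac_window_s[1] * cfg$rate_hz - 1e-9))):
    as.integer(floor(cfg$ac_window_s[2] * cfg$rate_hz + 1e-9))
  prof_mat <- do.call(cbind, unlist(lapply(per, function(p) {
    lapply(list(p$ac_front, p$ac_hind), function(a)
      if (is.null(a)) rep(NA_real_, length(k_grid)) else a$profile$values)
  }), recursive = FALSE))
  pooled_vals <- rowMeans(prof_mat, na.rm = TRUE)
  if (any(is.finite(pooled_vals))) {
    pooled_vals[!is.finite(pooled_vals)] <- NA_real_
    pooled_prof <- correlation_profile(k_grid / cfg$rate_hz, pooled_vals)
    global_T <- pooled_prof$peak_lag
  } else {
    # no bout long enough for the autocorrelation window: fall back to the
    # pooled mean step duration as the reference period
    pooled_prof <- NULL
    global_T <- mean(unlist(lapply(onsets, function(o)
      c(diff(o$front), diff(o$hind)))))
  }

  # phase angles on the reference period, anchored per bout and subject
  angles <- list()
  for (b in usable) {
    Tb <- if (cfg$per_bout_period && !is.null(per[[b]]$ac_front))
      mean(c(per[[b]]$ac_front$period, per[[b]]$ac_hind$period)) else global_T
    for (s in c("front", "hind")) {
      angles[[paste(b, s, sep = ".")]] <- if (cfg$angle_basis == "interval")
        to_phase_angles(diff(onsets[[b]][[s]]), Tb, t0 = 0, subject = s,
                        bout = b)
      else to_phase_angles(onsets[[b]][[s]], Tb, subject = s, bout = b)
    }
  }
  ang_front <- unlist(lapply(usable, function(b)
    as.numeric(angles[[paste0(b, ".front")]])))
  ang_hind <- unlist(lapply(usable, function(b)
    as.numeric(angles[[paste0(b, ".hind")]])))
  insufficient <- character()
  summ_front <- csum_or_na(ang_front)
  summ_hind <- csum_or_na(ang_hind)
  if (length(ang_front) < 2 || length(ang_hind) < 2)
    insufficient <- c(insufficient, "circular_summary")
  anova_subject <- if (length(ang_front) >= 2 && length(ang_hind) >= 2)
    circular_anova(list(front = ang_front, hind = ang_hind))
  else { insufficient <- c(insufficient, "circular_anova_subject"); NULL }
  by_bout <- lapply(usable, function(b)
    c(as.numeric(angles[[paste0(b, ".front")]]),
      as.numeric(angles[[paste0(b, ".hind")]])))
  names(by_bout) <- usable
  by_bout <- by_bout[vapply(by_bout, length, integer(1)) >= 2]
  anova_bout <- if (length(by_bout) >= 2) circular_anova(by_bout)
  else { insufficient <- c(insufficient, "circular_anova_bout"); NULL }
  # pair i-th front step with i-th hind step within each bout
  paired <- lapply(usable, function(b) {
    af <- as.numeric(angles[[paste0(b, ".front")]])
    ah <- as.numeric(angles[[paste0(b, ".hind")]])
    m <- min(length(af), length(ah))
    cbind(af[1:m], ah[1:m])
  })
  paired <- do.call(rbind, paired)
  rjs <- if (nrow(paired) >= 3)
    circular_correlation(paired[, 1], paired[, 2], cfg$n_boot, cfg$seed)
  else { insufficient <- c(insufficient, "circular_correlation"); NULL }

  # Granger leadership stage
  aic_total <- NULL
  if (cfg$granger_domain == "event") {
    global_p <- cfg$granger_event_lag
    granger <- lapply(seq_along(usable), function(i) {
      b <- usable[[i]]
      granger_events(onsets[[b]]$front, onsets[[b]]$hind,
                     p = cfg$granger_event_lag, alpha = cfg$alpha,
                     n_boot = cfg$granger_n_boot,
                     seed = (cfg$seed %||% 0) %% 1e6 * 1000 + i,
                     bout_id = b)
    })
  } else {
    # series domain: global AIC-selected VAR lag over bouts that support the
    # full candidate grid
    p_max <- as.integer(floor(cfg$granger_max_lag_s * cfg$rate_hz + 1e-9))
    supports <- vapply(per, function(p)
      length(p$series_front$values) > 5 * p_max + 3, logical(1))
    global_p <- p_max
    if (any(supports)) {
      aic_mat <- vapply(per[supports], function(p) {
        vapply(seq_len(p_max), function(q)
          tryCatch(fit_var(p$series_front, p$series_hind, q,
                           offset = p_max)$aic,
                   error = function(e) NA_real_),
          numeric(1))
      }, numeric(p_max))
      aic_mat <- as.matrix(aic_mat)
      ok <- colSums(is.na(aic_mat)) == 0  # drop degenerate bouts
      if (any(ok)) {
        aic_total <- rowSums(aic_mat[, ok, drop = FALSE])
        global_p <- which(aic_total <= min(aic_total) + 1e-12)[1]
      }
    }
    granger <- lapply(usable, function(b) {
      n <- length(per[[b]]$series_front$values)
      p_use <- min(global_p, max(1L, as.integer(floor((n - 3) / 5))))
      g <- granger_classify(per[[b]]$series_front, per[[b]]$series_hind,
                            lag = p_use / cfg$rate_hz, alpha = cfg$alpha,
                            bout_id = b)
      g$lag_truncated <- p_use < global_p
      g
    })
  }
  names(granger) <- usable
  if (cfg$p_adjust == "BH") {
    pf_adj <- stats::p.adjust(vapply(granger, `[[`, numeric(1), "p_front_to_hind"), "BH")
    ph_adj <- stats::p.adjust(vapply(granger, `[[`, numeric(1), "p_hind_to_front"), "BH")
    for (i in seq_along(granger)) {
      g <- granger[[i]]
      sig_f <- !is.na(pf_adj[i]) && pf_adj[i] < cfg$alpha
      sig_h <- !is.na(ph_adj[i]) && ph_adj[i] < cfg$alpha
      g$classification <- if (g$degenerate) "none"
        else if (sig_f && sig_h) "bidirectional"
        else if (sig_f) "front_leads" else if (sig_h) "hind_leads" else "none"
      granger[[i]] <- g
    }
  }
  classes <- vapply(granger, `[[`, character(1), "classification")
  granger_counts <- vapply(c("front_leads", "hind_leads", "bidirectional", "none"),
                           function(k) sum(classes == k), integer(1))

  bouts_df <- do.call(rbind, lapply(usable, function(b) {
    p <- per[[b]]; of <- onsets[[b]]$front; oh <- onsets[[b]]$hind
    data.frame(
      bout = b, duration = p$duration,
      n_steps_front = length(of), n_steps_hind = length(oh),
      mean_step_front = mean(diff(of)), mean_step_hind = mean(diff(oh)),
      ac_period_front = if (is.null(p$ac_front)) NA_real_ else p$ac_front$period,
      ac_period_hind = if (is.null(p$ac_hind)) NA_real_ else p$ac_hind$period,
      xc_max_lag = if (is.null(p$xc)) NA_real_ else p$xc$lag,
      mean_angle_front = csum_or_na(angles[[paste0(b, ".front")]])$mean_angle,
      mean_angle_hind = csum_or_na(angles[[paste0(b, ".hind")]])$mean_angle,
      R_bar_front = csum_or_na(angles[[paste0(b, ".front")]])$R_bar,
      R_bar_hind = csum_or_na(angles[[paste0(b, ".hind")]])$R_bar,
      granger_class = classes[b], stringsAsFactors = FALSE)
  }))
  rownames(bouts_df) <- NULL

  steps_front <- unlist(lapply(usable, function(b) diff(onsets[[b]]$front)))
  steps_hind <- unlist(lapply(usable, function(b) diff(onsets[[b]]$hind)))
  steps_all <- c(steps_front, steps_hind)
  tempo_vs_ref <- if (length(steps_all) >= 2 && stats::sd(steps_all) > 1e-9) {
    tv <- lapply(seq_along(cfg$reference_tempi), function(i)
      compare_tempo(steps_all, cfg$reference_tempi[i],
                    names(cfg$reference_tempi)[i]))
    names(tv) <- names(cfg$reference_tempi)
    tv
  } else { insufficient <- c(insufficient, "tempo_vs_reference"); NULL }

  xl <- bouts_df$xc_max_lag[!is.na(bouts_df$xc_max_lag)]
  acb <- c(bouts_df$ac_period_front, bouts_df$ac_period_hind)
  acb <- acb[!is.na(acb)]
  aggregate <- list(
    n_bouts = length(usable),
    n_steps = length(steps_all) + 2L * length(usable),
    mean_bout_duration = mean(bouts_df$duration),
    min_bout_duration = min(bouts_df$duration),
    max_bout_duration = max(bouts_df$duration),
    sd_bout_duration = if (length(usable) > 1) stats::sd(bouts_df$duration) else NA_real_,
    pooled_mean_tempo = mean(steps_all),
    tempo_sd_front = if (length(steps_front) > 1) stats::sd(steps_front) else NA_real_,
    tempo_sd_hind = if (length(steps_hind) > 1) stats::sd(steps_hind) else NA_real_,
    bout_mean_tempo_range = range(c(bouts_df$mean_step_front,
                                    bouts_df$mean_step_hind)),
    pooled_ac_period = global_T,
    median_ac_period = if (length(acb)) median(acb) else NA_real_,
    sd_ac_period = if (length(acb) > 1) stats::sd(acb) else NA_real_,
    modal_xc_lag = if (length(xl)) {
      tb <- table(xl); as.numeric(names(tb)[which.max(tb)])
    } else NA_real_,
    mean_xc_lag = if (length(xl)) mean(xl) else NA_real_,
    sd_xc_lag = if (length(xl) > 1) stats::sd(xl) else NA_real_,
    circ_front = summ_front, circ_hind = summ_hind,
    circ_anova_subject = anova_subject, circ_anova_bout = anova_bout,
    r_js = rjs,
    granger_domain = cfg$granger_domain,
    granger_optimal_lag = if (cfg$granger_domain == "series")
      global_p / cfg$rate_hz else global_p,
    granger_counts = as.list(granger_counts),
    tempo_vs_reference = tempo_vs_ref,
    insufficient = insufficient)

  structure(list(bouts = bouts_df, aggregate = aggregate, angles = angles,
                 granger = granger, pooled_ac_profile = pooled_prof,
                 granger_aic = aic_total, excluded_bouts = excluded,
                 config = cfg),
            class = "entrain_report")
}

#' @export
print.entrain_report <- function(x, ...) {
  a <- x$aggregate
  cat("<entrain_report>\n")
  cat(sprintf("  bouts analysed: %d (excluded: %d); mean duration %.1f s [%.2f, %.2f]\n",
              a$n_bouts, length(x$excluded_bouts), a$mean_bout_duration,
              a$min_bout_duration, a$max_bout_duration))
  cat(sprintf("  pooled tempo %.3f s; pooled autocorrelation period %.3f s; modal XC lag %.4g s\n",
              a$pooled_mean_tempo, a$pooled_ac_period, a$modal_xc_lag))
  cat(sprintf("  mean angle front %.1f deg (R_bar %.2f), hind %.1f deg (R_bar %.2f)\n",
              a$circ_front$mean_angle, a$circ_front$R_bar,
              a$circ_hind$mean_angle, a$circ_hind$R_bar))
  if (!is.null(a$r_js))
    cat(sprintf("  r_JS = %.3f [%.3f, %.3f]\n", a$r_js$r_js,
                a$r_js$ci95[1], a$r_js$ci95[2]))
  gc <- a$granger_counts
  lag_txt <- if (a$granger_domain == "series")
    sprintf("lag %.2f s", a$granger_optimal_lag)
  else sprintf("%d-lag phase correction", a$granger_optimal_lag)
  cat(sprintf("  Granger (%s): front %d / hind %d / bidirectional %d / none %d\n",
              lag_txt, gc$front_leads, gc$hind_leads,
              gc$bidirectional, gc$none))
  invisible(x)
}

# Flatten S3 stat objects into plain lists for serialization.
flatten_aggregate <- function(a) {
  strip <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, c("circular_summary", "circ_anova", "circ_corr")))
      return(unclass(x))
    x
  }
  lapply(a, function(x) {
    if (is.list(x) && !is.null(names(x)) &&
        all(vapply(x, is.list, logical(1)))) lapply(x, strip)
    else strip(x)
  })
}

#' Render an analysis report
#'
#' Serializes an [analyze_dataset()] result as machine-readable JSON or a
#' short human-readable Markdown summary; both echo the configuration (and
#' its seed) for reproducibility.
#'
#' @param x An `entrain_report`.
#' @param format `"json"` or `"markdown"`.
#' @param path Optional output file; when `NULL` the rendering is returned
#'   as a character string.
#' @return The rendering, invisibly when written to `path`.
#' @export
render_report <- function(x, format = c("json", "markdown"), path = NULL) {
  stopifnot(inherits(x, "entrain_report"))
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(aggregate = flatten_aggregate(x$aggregate),
                    bouts = x$bouts, excluded_bouts = x$excluded_bouts,
                    config = unclass(x$config))
    out <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            null = "null", pretty = TRUE)
  } else {
    a <- x$aggregate
    gc <- a$granger_counts
    lines <- c(
      "# Dyadic entrainment report", "",
      sprintf("- Bouts analysed: %d (excluded: %d)", a$n_bouts,
              length(x$excluded_bouts)),
      sprintf("- Bout duration: mean %.1f s (min %.2f, max %.2f, SD %.1f)",
              a$mean_bout_duration, a$min_bout_duration, a$max_bout_duration,
              a$sd_bout_duration),
      sprintf("- Pooled step tempo: %.2f s (SD front %.3f, hind %.3f)",
              a$pooled_mean_tempo, a$tempo_sd_front, a$tempo_sd_hind),
      sprintf("- Pooled autocorrelation period: %.2f s (per-bout median %.2f, SD %.3f)",
              a$pooled_ac_period, a$median_ac_period, a$sd_ac_period),
      sprintf("- Cross-correlation max lag: modal %.4g s (mean %.4f, SD %.4f)",
              a$modal_xc_lag, a$mean_xc_lag, a$sd_xc_lag),
      sprintf("- Mean angle: front %.1f deg (R_bar %.2f, Rayleigh p %.2g); hind %.1f deg (R_bar %.2f, Rayleigh p %.2g)",
              a$circ_front$mean_angle, a$circ_front$R_bar, a$circ_front$rayleigh_p,
              a$circ_hind$mean_angle, a$circ_hind$R_bar, a$circ_hind$rayleigh_p),
      if (!is.null(a$r_js))
        sprintf("- r_JS = %.3f (p = %.2g, CI95 %.3f-%.3f)", a$r_js$r_js,
                a$r_js$p, a$r_js$ci95[1], a$r_js$ci95[2]),
      sprintf("- Granger (%s domain): front leads %d, hind leads %d, bidirectional %d, none %d",
              a$granger_domain, gc$front_leads, gc$hind_leads,
              gc$bidirectional, gc$none),
      sprintf("- Seed: %s", x$config$seed %||% "none"))
    out <- paste(lines[!vapply(lines, is.null, logical(1))], collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Per-bout Granger table
#' @param x An `entrain_report`.
#' @param path Optional TSV path.
#' @return Data frame: bout, lag used, F and p per direction, classification.
#' @export
granger_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "entrain_report"))
  df <- do.call(rbind, lapply(x$granger, function(g)
    data.frame(bout = g$bout_id, lag_used_s = g$lag_used,
               F_f2h = g$stat_f2h, p_f2h = g$p_front_to_hind,
               F_h2f = g$stat_h2f, p_h2f = g$p_hind_to_front,
               classification = g$classification,
               degenerate = g$degenerate, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
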