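#' Construct a step-onset dataset
#'
#' A `step_dataset` holds annotated footfall onsets for a dyad, one row per
#' step, partitioned by bout and subject role. Rows are stored sorted by bout
#' (order of first appearance) and onset time; input order is never trusted.
#'
#' @param time Numeric vector of onset times in seconds (non-negative).
#' @param subject Character vector of role labels, each `"front"` or `"hind"`.
#' @param bout Character vector of bout identifiers.
#' @param provenance Optional free-text metadata (source file, annotator id).
#' @return An object of class `step_dataset`: a `data.frame` with columns
#'   `bout`, `subject`, `time` and a `provenance` attribute.
#' @examples
#' d <- step_dataset(c(0, 0.9, 0.02, 0.91),
#'                   c("front", "front", "hind", "hind"),
#'                   rep("b1", 4))
#' bout_onsets(d, "b1", "front")
#' @export
step_dataset <- function(time, subject, bout, provenance = character()) {
  if (length(time) != length(subject) || length(time) != length(bout))
    stop("`time`, `subject` and `bout` must have equal length")
  time <- as.numeric(time)
  subject <- as.character(subject)
  bout <- as.character(bout)
  if (length(time) > 0 && (anyNA(time) || any(time < 0)))
    stop("onset times must be non-negative and non-missing")
  bad <- setdiff(unique(subject), c("front", "hind"))
  if (length(bad) > 0)
    stop("subject labels must be 'front' or 'hind'; found: ",
         paste(bad, collapse = ", "))
  bout_order <- unique(bout)
  ord <- order(match(bout, bout_order), time, subject)
  d <- data.frame(bout = bout[ord], subject = subject[ord], time = time[ord],
                  stringsAsFactors = FALSE)
  # duplicate timestamps within one subject's train are physically impossible
  for (b in bout_order) {
    for (s in c("front", "hind")) {
      tt <- d$time[d$bout == b & d$subject == s]
      if (anyDuplicated(tt))
        stop("duplicate onset times for subject '", s, "' in bout '", b, "'")
    }
  }
  structure(d, provenance = provenance,
            class = c("step_dataset", "data.frame"))
}

#' @export
print.step_dataset <- function(x, ...) {
  cat("<step_dataset> ", length(bout_ids(x)), " bout(s), ",
      nrow(x), " step onsets\n", sep = "")
  prov <- attr(x, "provenance")
  if (length(prov) > 0) cat("provenance:", paste(prov, collapse = "; "), "\n")
  invisible(x)
}

#' Bout identifiers of a dataset, in stored order
#' @param d A `step_dataset`.
#' @return Character vector of bout ids.
#' @export
bout_ids <- function(d) unique(d$bout)

#' Onset times for one subject in one bout
#' @param d A `step_dataset`.
#' @param bout Bout identifier.
#' @param subject `"front"` or `"hind"`.
#' @return Sorted numeric vector of onset times (seconds).
#' @export
bout_onsets <- function(d, bout, subject) {
  sort(d$time[d$bout == bout & d$subject == subject])
}

#' Per-bout durations
#'
#' Duration of a bout is the span from the first to the last onset across
#' both subjects.
#' @param d A `step_dataset`.
#' @return Named numeric vector, seconds, one entry per bout.
#' @export
bout_durations <- function(d) {
  vapply(bout_ids(d), function(b) {
    tt <- d$time[d$bout == b]
    max(tt) - min(tt)
  }, numeric(1))
}

#' Read a step-onset annotation CSV
#'
#' Reads event-logger style exports: one row per footfall with onset time in
#' seconds, subject role, and bout identifier. Column names are configurable;
#' extra columns (e.g. a `date` metadata column) are ignored. Onsets are
#' re-sorted on read, so file row order does not matter.
#'
#' @param path Path to a CSV file with a header row.
#' @param time_col,subject_col,bout_col Column names holding onset time,
#'   subject role and bout id (defaults `"time"`, `"subject"`, `"bout"`).
#' @return A [step_dataset()].
#' @export
read_step_events <- function(path, time_col = "time", subject_col = "subject",
                             bout_col = "bout") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c(time_col, subject_col, bout_col)
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  step_dataset(as.numeric(raw[[time_col]]), raw[[subject_col]],
               raw[[bout_col]], provenance = path)
}

#' Write a step-onset dataset as CSV
#'
#' Times are serialized at millisecond precision (three decimals), finer than
#' the ~0.04 s frame resolution of typical video annotation. A dataset whose
#' times are already millisecond-rounded (as produced by [simulate_dyad()])
#' round-trips exactly through [read_step_events()].
#'
#' @param d A [step_dataset()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_step_events <- function(d, path) {
  stopifnot(inherits(d, "step_dataset"))
  out <- data.frame(time = sprintf("%.3f", d$time), subject = d$subject,
                    bout = d$bout, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

# Greedy one-to-one matching of two onset vectors: repeatedly pair the two
# closest unmatched onsets with |x - y| <= tol. Symmetric in its arguments.
match_onsets <- function(x, y, tol) {
  if (length(x) == 0 || length(y) == 0)
    return(data.frame(i = integer(), j = integer(), diff = numeric()))
  d <- abs(outer(x, y, "-"))
  i_out <- integer(); j_out <- integer()
  repeat {
    k <- which.min(d)
    if (length(k) == 0 || !is.finite(d[k]) || d[k] > tol) break
    ij <- arrayInd(k, dim(d))
    i_out <- c(i_out, ij[1]); j_out <- c(j_out, ij[2])
    d[ij[1], ] <- Inf
    d[, ij[2]] <- Inf
  }
  data.frame(i = i_out, j = j_out, diff = y[j_out] - x[i_out])
}

#' Inter-annotator reliability of step-onset timings
#'
#' Matches the onsets of two annotation sets of the same recordings, bout by
#' bout and subject by subject, by greedy nearest-neighbour pairing within a
#' tolerance (one-to-one; unmatched onsets are counted, not penalized), and
#' summarizes the timing discrepancies: median absolute difference, standard
#' deviation of signed differences, and an Anderson-Darling statistic of the
#' signed differences against a normal with estimated mean and SD.
#'
#' @param a,b Two [step_dataset()] objects sharing at least one bout id.
#' @param tolerance Maximum |difference| (seconds) for two onsets to be
#'   considered the same step; default 0.5 s, robust to missed steps.
#' @return An object of class `reliability_report`: list with `n_pairs`,
#'   `median_abs_diff`, `sd_diff`, `ad_statistic`, `ad_p`, `unmatched_a`,
#'   `unmatched_b`, and the signed differences `diffs` (b minus a, seconds).
#'   The Anderson-Darling entries are `NA` when fewer than 8 pairs or when
#'   all differences are identical.
#' @export
reliability <- function(a, b, tolerance = 0.5) {
  stopifnot(inherits(a, "step_dataset"), inherits(b, "step_dataset"))
  if (!is.numeric(tolerance) || tolerance <= 0) stop("tolerance must be > 0")
  shared <- intersect(bout_ids(a), bout_ids(b))
  if (length(shared) == 0) stop("datasets share no bout ids")
  diffs <- numeric(); un_a <- 0L; un_b <- 0L
  for (bt in shared) {
    for (s in c("front", "hind")) {
      xa <- bout_onsets(a, bt, s)
      xb <- bout_onsets(b, bt, s)
      m <- match_onsets(xa, xb, tolerance)
      diffs <- c(diffs, m$diff)
      un_a <- un_a + length(xa) - nrow(m)
      un_b <- un_b + length(xb) - nrow(m)
    }
  }
  ad_stat <- NA_real_; ad_p <- NA_real_
  if (length(diffs) >= 8 && stats::sd(diffs) > 0) {
    ad <- nortest::ad.test(diffs)
    ad_stat <- unname(ad$statistic); ad_p <- ad$p.value
  }
  structure(list(n_pairs = length(diffs),
                 median_abs_diff = if (length(diffs)) median(abs(diffs)) else NA_real_,
                 sd_diff = if (length(diffs) > 1) stats::sd(diffs) else 0,
                 ad_statistic = ad_stat, ad_p = ad_p,
                 unmatched_a = un_a, unmatched_b = un_b, diffs = diffs),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat("<reliability_report>\n")
  cat(sprintf("  matched pairs: %d (unmatched: %d / %d)\n",
              x$n_pairs, x$unmatched_a, x$unmatched_b))
  cat(sprintf("  median |diff|: %.4f s, SD of signed diffs: %.4f s\n",
              x$median_abs_diff, x$sd_diff))
  if (!is.na(x$ad_statistic))
    cat(sprintf("  Anderson-Darling: A = %.3f, p = %.3g\n",
                x$ad_statistic, x$ad_p))
  invisible(x)
}
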