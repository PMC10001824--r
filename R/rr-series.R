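#' Beat-to-beat R-R interval series
#'
#' Container for a tachogram: the sequence of beat-to-beat (R-R) intervals of
#' a single continuous recording, in milliseconds, together with the identity
#' of the recording (subject, session, pre/post-exercise condition). Beat
#' onset times are derived as the cumulative sum of the intervals and exposed
#' in seconds.
#'
#' @param intervals Numeric vector of strictly positive R-R intervals (ms),
#'   length at least 2.
#' @param subject_id Opaque subject label.
#' @param condition `"pre"` or `"post"` (relative to the exercise bout).
#' @param session Session number, `1` or `2`.
#'
#' @return An object of class `rr_series`: a list with elements `intervals`
#'   (ms), `cumulative_time` (beat onset times, s), `subject_id`, `condition`
#'   and `session`.
#' @examples
#' rr <- rr_series(c(800, 810, 790, 805, 795))
#' rr$cumulative_time
#' @export
rr_series <- function(intervals, subject_id = NA_character_,
                      condition = c("pre", "post"), session = 1L) {
  condition <- match.arg(condition)
  intervals <- as.numeric(intervals)
  if (length(intervals) < 2L)
    stop_hrv("invalid_input", "an R-R series needs at least 2 intervals, got %d",
             length(intervals))
  if (anyNA(intervals) || any(!is.finite(intervals)))
    stop_hrv("invalid_input", "R-R intervals must be finite and non-missing")
  if (any(intervals <= 0))
    stop_hrv("invalid_input", "R-R intervals must be strictly positive")
  if (!session %in% c(1L, 2L))
    stop_hrv("invalid_input", "session must be 1 or 2")
  structure(
    list(
      intervals = intervals,
      cumulative_time = cumsum(intervals) / 1000,
      subject_id = as.character(subject_id),
      condition = condition,
      session = as.integer(session)
    ),
    class = "rr_series"
  )
}

#' @export
print.rr_series <- function(x, ...) {
  dur <- x$cumulative_time[length(x$cumulative_time)]
  cat(sprintf(
    "<rr_series> %d beats, %.1f s, mean RR %.1f ms (subject %s, session %d, %s)\n",
    length(x$intervals), dur, mean(x$intervals), x$subject_id, x$session,
    x$condition))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

is_rr_series <- function(x) inherits(x, "rr_series")

# Rebuild a series with new intervals, keeping its identity.
rr_replace <- function(series, intervals) {
  rr_series(intervals, subject_id = series$subject_id,
            condition = series$condition, session = series$session)
}

#' Total duration of an R-R series
#'
#' @param series An [rr_series()].
#' @return Duration in seconds (sum of all intervals).
#' @export
rr_duration <- function(series) {
  stopifnot(is_rr_series(series))
  series$cumulative_time[length(series$intervals)]
}

#' Select a contiguous analysis window from a recording
#'
#' Short-term HRV analysis conventionally uses a 5-minute segment taken from
#' a longer rest recording. This extracts the contiguous beats whose onsets
#' fall in the trailing (`anchor = "last"`, the default) or leading
#' (`anchor = "first"`) window of `window_s` seconds.
#'
#' @param series An [rr_series()].
#' @param window_s Window length in seconds (default 300, i.e. 5 minutes).
#' @param anchor `"last"` (trailing window, default) or `"first"`.
#' @return An [rr_series()] restricted to the window.
#' @examples
#' rr <- rr_series(rep(1000, 600))           # 10 minutes of 1 s beats
#' length(select_segment(rr, 300)$intervals) # the final 5 minutes
#' @export
select_segment <- function(series, window_s = 300, anchor = c("last", "first")) {
  stopifnot(is_rr_series(series))
  anchor <- match.arg(anchor)
  if (window_s <= 0)
    stop_hrv("invalid_input", "window_s must be positive")
  total <- rr_duration(series)
  if (total < window_s)
    stop_hrv("insufficient_recording",
             "recording lasts %.1f s, shorter than the %.1f s analysis window",
             total, window_s, data = list(available_s = total))
  onset <- series$cumulative_time
  keep <- if (anchor == "last") {
    onset >= (total - window_s)
  } else {
    onset < window_s
  }
  rr_replace(series, series$intervals[keep])
}

#' Remove artifacts and ectopic beats from an R-R series
#'
#' Flags beats whose interval deviates from a running local median (11-beat
#' window) by more than `deviation_threshold` (as a fraction of the local
#' median) and removes them. Removal, rather than interpolation, is used so
#' that retained beats are untouched measurements. The report states whether
#' the flagged fraction exceeds the 3% budget conventionally regarded as the
#' limit for a usable short-term recording.
#'
#' @param series An [rr_series()].
#' @param deviation_threshold Maximum tolerated relative deviation from the
#'   running local median, in (0, 1). Default 0.25.
#' @param artifact_budget Fraction of flagged beats above which the recording
#'   is marked as exceeding the artifact budget. Default 0.03.
#' @return A list with elements `series` (the cleaned [rr_series()]) and
#'   `report`, a `cleaning_report` with `n_original`, `n_flagged`,
#'   `flagged_indices`, `artifact_fraction` and `exceeded_threshold`.
#' @examples
#' rr <- rr_series(c(rep(800, 150), 1600, rep(800, 150)))
#' clean_rr(rr)$report$n_flagged
#' @export
clean_rr <- function(series, deviation_threshold = 0.25, artifact_budget = 0.03) {
  stopifnot(is_rr_series(series))
  if (deviation_threshold <= 0 || deviation_threshold >= 1)
    stop_hrv("invalid_input", "deviation_threshold must be in (0, 1)")
  x <- series$intervals
  n <- length(x)
  if (n < 5L)
    stop_hrv("invalid_input", "cleaning needs at least 5 beats, got %d", n)
  local_med <- stats::runmed(x, k = 11L, endrule = "median")
  flagged <- which(abs(x - local_med) / local_med > deviation_threshold)
  if (length(flagged) == n)
    stop_hrv("degenerate_series", "all %d beats were flagged as artifacts", n)
  report <- structure(
    list(
      n_original = n,
      n_flagged = length(flagged),
      flagged_indices = flagged,
      artifact_fraction = length(flagged) / n,
      exceeded_threshold = (length(flagged) / n) > artifact_budget
    ),
    class = "cleaning_report"
  )
  cleaned <- if (length(flagged)) rr_replace(series, x[-flagged]) else series
  list(series = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d / %d beats flagged (%.2f%%)%s\n",
              x$n_flagged, x$n_original, 100 * x$artifact_fraction,
              if (x$exceeded_threshold) " — exceeds the 3% artifact budget" else ""))
  invisible(x)
}
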