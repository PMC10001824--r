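#' Time-domain HRV indices
#'
#' Computes the arithmetic mean R-R interval, the mean heart rate, RMSSD
#' (root mean square of successive R-R differences, the classic vagal index)
#' and SDNN (standard deviation of the R-R intervals, reflecting total
#' variability). SDNN uses the sample (n - 1) denominator.
#'
#' @param series An [rr_series()] with at least 3 beats.
#' @return A named list: `mean_rr` (ms), `hr_mean` (bpm), `rmssd` (ms),
#'   `sdnn` (ms).
#' @examples
#' time_domain(rr_series(c(800, 810, 790, 805, 795)))
#' @export
time_domain <- function(series) {
  stopifnot(is_rr_series(series))
  x <- series$intervals
  if (length(x) < 3L)
    stop_hrv("invalid_input", "time-domain indices need at least 3 beats, got %d",
             length(x))
  d <- diff(x)
  list(
    mean_rr = mean(x),
    hr_mean = 60000 / mean(x),
    rmssd = sqrt(mean(d^2)),
    sdnn = stats::sd(x)
  )
}

#' Poincare plot descriptors SD1 and SD2
#'
#' Spread of the lag-1 Poincare scatter (RR\[i\], RR\[i+1\]) along the axes
#' rotated by 45 degrees: SD1 is the short-axis (beat-to-beat) spread,
#' measured about the line of identity, and SD2 the long-axis spread,
#' measured about the scatter centroid. With these conventions
#' SD1 = RMSSD / sqrt(2) exactly.
#'
#' @param series An [rr_series()] with at least 3 beats.
#' @return A named list with `sd1` and `sd2` (ms).
#' @export
poincare <- function(series) {
  stopifnot(is_rr_series(series))
  x <- series$intervals
  if (length(x) < 3L)
    stop_hrv("invalid_input", "Poincare indices need at least 3 beats, got %d",
             length(x))
  a <- x[-length(x)]
  b <- x[-1]
  # short axis: perpendicular distance to the identity line (no centring)
  u <- (b - a) / sqrt(2)
  # long axis: spread along the identity direction, about the centroid
  v <- (b + a) / sqrt(2)
  list(sd1 = sqrt(mean(u^2)), sd2 = sqrt(mean((v - mean(v))^2)))
}

#' Baevsky's stress index
#'
#' Histogram-based sympathetic load index
#' `SI = AMo / (2 * Mo * MxDMn)`, where `Mo` is the modal bin centre of the
#' R-R distribution in seconds, `AMo` the percentage of intervals falling in
#' the modal bin, and `MxDMn` the interval range (max - min) in seconds.
#' Downstream reporting conventionally uses the square root of SI as the
#' "stress index".
#'
#' @param series An [rr_series()].
#' @param bin_width_ms Histogram bin width in ms (default 50, the standard
#'   choice for SI).
#' @return The stress index (dimensionless).
#' @export
baevsky_si <- function(series, bin_width_ms = 50) {
  stopifnot(is_rr_series(series))
  if (bin_width_ms <= 0)
    stop_hrv("invalid_input", "bin_width_ms must be positive")
  x <- series$intervals
  rng <- range(x)
  mxdmn_s <- (rng[2] - rng[1]) / 1000
  if (mxdmn_s == 0)
    stop_hrv("degenerate_distribution",
             "constant R-R series: MxDMn = 0, stress index undefined")
  breaks <- seq(floor(rng[1] / bin_width_ms) * bin_width_ms,
                ceiling(rng[2] / bin_width_ms) * bin_width_ms,
                by = bin_width_ms)
  if (length(breaks) < 2L) breaks <- c(breaks, breaks + bin_width_ms)
  counts <- hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  k <- which.max(counts$counts)
  mo_s <- counts$mids[k] / 1000
  amo_pct <- 100 * counts$counts[k] / length(x)
  amo_pct / (2 * mo_s * mxdmn_s)
}

#' Population reference values for the composite autonomic indices
#'
#' The parasympathetic (PNS) and sympathetic (SNS) composite indices express
#' a recording's mean R-R, RMSSD, SD1, Baevsky SI and SD2 as standard
#' deviations above or below a "normal population" average. The reference
#' constants used by commercial HRV software are proprietary, so this ships
#' a documented default anchored to published resting norms for healthy
#' adults; index values are norm-relative and comparable only within one
#' reference.
#'
#' @param mean_rr,rmssd,sd1,sd2,baevsky_si Numeric `c(mean, sd)` pairs.
#' @param source Free-text label recording where the constants come from.
#' @return A `norm_reference` object (list of mean/sd pairs).
#' @export
norm_reference <- function(mean_rr = c(926, 90),
                           rmssd = c(42, 15),
                           sd1 = c(29.7, 10.6),
                           sd2 = c(66, 20),
                           baevsky_si = c(100, 50),
                           source = "package default (published resting norms)") {
  vals <- list(mean_rr = mean_rr, rmssd = rmssd, sd1 = sd1, sd2 = sd2,
               baevsky_si = baevsky_si)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 2L || anyNA(v) || v[2] <= 0)
      stop_hrv("configuration",
               "norm entry '%s' must be c(mean, sd) with sd > 0", nm)
  }
  structure(c(vals, list(source = source)), class = "norm_reference")
}

#' Composite parasympathetic and sympathetic indices
#'
#' PNS index: mean of the z-scores of mean R-R, RMSSD and SD1 relative to
#' the population reference — all three rise with vagal activity, so larger
#' is more parasympathetic. SNS index: mean of the z-scores of mean R-R
#' (sign-flipped: sympathetic activation shortens R-R), Baevsky SI, and SD2
#' (sign-flipped: sympathetic dominance suppresses overall variability) —
#' oriented so that larger means more sympathetic.
#'
#' @param features An `hrv_features` object, or a named list providing
#'   `mean_rr`, `rmssd`, `sd1`, `sd2` and `baevsky_si`.
#' @param norms A [norm_reference()].
#' @return A named list with `pns_index` and `sns_index`.
#' @export
autonomic_indices <- function(features, norms = norm_reference()) {
  stopifnot(inherits(norms, "norm_reference"))
  need <- c("mean_rr", "rmssd", "sd1", "sd2", "baevsky_si")
  for (nm in need) {
    if (is.null(features[[nm]]) || !is.finite(features[[nm]]))
      stop_hrv("configuration", "feature '%s' missing for autonomic indices", nm)
    if (is.null(norms[[nm]]))
      stop_hrv("configuration", "norm entry '%s' missing", nm)
  }
  z <- function(nm) (features[[nm]] - norms[[nm]][1]) / norms[[nm]][2]
  list(
    pns_index = mean(c(z("mean_rr"), z("rmssd"), z("sd1"))),
    sns_index = mean(c(-z("mean_rr"), z("baevsky_si"), -z("sd2")))
  )
}

#' Percentage of age-predicted maximum heart rate
#'
#' Expresses a heart rate as a percentage of the age-predicted maximum,
#' the usual way of stating the relative intensity reached during an
#' exercise test. The default prediction is the classic 220 - age;
#' the Tanaka formula 208 - 0.7 * age is also available.
#'
#' @param hr_mean Heart rate in bpm (> 0).
#' @param age Age in years (40 to 110).
#' @param formula `"fox"` (220 - age, default) or `"tanaka"`
#'   (208 - 0.7 * age).
#' @return Percentage of predicted maximum heart rate.
#' @examples
#' pct_hrmax(100, age = 70)  # 66.7% of 150 bpm
#' @export
pct_hrmax <- function(hr_mean, age, formula = c("fox", "tanaka")) {
  formula <- match.arg(formula)
  if (any(!is.finite(hr_mean)) || any(hr_mean <= 0))
    stop_hrv("invalid_input", "hr_mean must be positive")
  if (any(!is.finite(age)) || any(age < 40) || any(age > 110))
    stop_hrv("invalid_input", "age must be between 40 and 110 years")
  hrmax <- switch(formula, fox = 220 - age, tanaka = 208 - 0.7 * age)
  100 * hr_mean / hrmax
}

#' Full HRV feature set for one recording
#'
#' Runs the whole per-recording pipeline: artifact cleaning, selection of
#' the trailing analysis window, then the time-domain, Poincare, spectral
#' and composite indices. Deterministic given its inputs.
#'
#' @param series A raw [rr_series()].
#' @param config A [spectral_config()].
#' @param norms A [norm_reference()] for the composite indices.
#' @param age Subject age in years, used for `pct_hrmax`; `NULL` to skip.
#' @param deviation_threshold Cleaning threshold passed to [clean_rr()].
#' @param window_s Analysis window in seconds passed to [select_segment()];
#'   `NULL` analyses the full cleaned recording.
#' @param hrmax_formula Passed to [pct_hrmax()].
#' @return An `hrv_features` object: named list of all indices, with the
#'   cleaning report in `attr(, "cleaning")` and the recording identity in
#'   `attr(, "recording")`.
#' @export
compute_all <- function(series, config = spectral_config(),
                        norms = norm_reference(), age = NULL,
                        deviation_threshold = 0.25, window_s = 300,
                        hrmax_formula = "fox") {
  stopifnot(is_rr_series(series))
  cleaned <- withCallingHandlers(
    clean_rr(series, deviation_threshold),
    hrv_error = function(e) stop_hrv("stage_failure", "cleaning: %s",
                                     conditionMessage(e))
  )
  seg <- if (is.null(window_s)) cleaned$series else
    withCallingHandlers(
      select_segment(cleaned$series, window_s),
      hrv_error = function(e) stop_hrv("stage_failure", "segment selection: %s",
                                       conditionMessage(e))
    )
  td <- time_domain(seg)
  pc <- poincare(seg)
  sp <- spectral_powers(seg, config)
  si <- baevsky_si(seg)
  base <- c(td, pc,
            list(vlf_power = sp$vlf_power, lf_power = sp$lf_power,
                 hf_power = sp$hf_power, baevsky_si = si,
                 stress_index = sqrt(si)))
  auton <- autonomic_indices(base, norms)
  out <- c(base, auton,
           list(pct_hrmax = if (is.null(age)) NA_real_ else
             pct_hrmax(td$hr_mean, age, hrmax_formula)))
  structure(out, class = "hrv_features",
            cleaning = cleaned$report,
            unreliable_bands = attr(sp, "unreliable"),
            recording = list(subject_id = series$subject_id,
                             session = series$session,
                             condition = series$condition))
}

#' @export
print.hrv_features <- function(x, ...) {
  cat("<hrv_features>\n")
  vals <- unclass(x)
  for (nm in names(vals))
    cat(sprintf("  %-12s %s\n", nm, format(vals[[nm]], digits = 5)))
  cl <- attr(x, "cleaning")
  if (!is.null(cl) && cl$exceeded_threshold)
    cat("  ! artifact fraction exceeds the 3% budget\n")
  invisible(x)
}
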