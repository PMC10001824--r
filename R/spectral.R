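#' Configuration for frequency-domain HRV analysis
#'
#' Band edges follow the conventional short-term HRV bands: VLF
#' 0.003-0.04 Hz, LF 0.04-0.15 Hz, HF 0.15-0.40 Hz. The unevenly sampled
#' tachogram is either cubic-spline resampled onto a uniform 4 Hz grid and
#' analysed with a Welch periodogram (default), or analysed directly with a
#' Lomb-Scargle periodogram.
#'
#' @param vlf_band,lf_band,hf_band Numeric length-2 band edges in Hz;
#'   bands must be ordered, disjoint and of positive width.
#' @param resample_rate Uniform resampling rate in Hz (Welch only).
#' @param detrend `"linear"` (default), `"none"`.
#' @param estimator `"welch"` (default) or `"lomb_scargle"`.
#' @return A `spectral_config` object.
#' @export
spectral_config <- function(vlf_band = c(0.003, 0.04),
                            lf_band = c(0.04, 0.15),
                            hf_band = c(0.15, 0.40),
                            resample_rate = 4,
                            detrend = c("linear", "none"),
                            estimator = c("welch", "lomb_scargle")) {
  detrend <- match.arg(detrend)
  estimator <- match.arg(estimator)
  bands <- list(vlf = vlf_band, lf = lf_band, hf = hf_band)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2L || b[1] >= b[2] || b[1] < 0)
      stop_hrv("configuration", "band '%s' must be an increasing Hz interval", nm)
  }
  edges <- unlist(bands)
  if (is.unsorted(edges))
    stop_hrv("configuration", "bands must be ordered VLF < LF < HF and disjoint")
  if (resample_rate <= 2 * hf_band[2])
    stop_hrv("configuration",
             "resample_rate must exceed twice the upper HF edge (Nyquist)")
  structure(list(vlf_band = vlf_band, lf_band = lf_band, hf_band = hf_band,
                 resample_rate = resample_rate, detrend = detrend,
                 estimator = estimator),
            class = "spectral_config")
}

# Welch PSD with Hann windows and 50% overlap; density scaling so that the
# integral over frequency recovers the signal variance (units ms^2/Hz).
welch_psd <- function(x, fs, nperseg = NULL) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- max(64L, min(n, ceiling(n / 2)))
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  u <- mean(w^2)
  nf <- floor(nperseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- seg - mean(seg)
    sp <- abs(stats::fft(seg * w)[seq_len(nf)])^2
    acc <- acc + sp
  }
  psd <- acc / length(starts) / (fs * nperseg * u)
  # one-sided: double everything except DC (and Nyquist for even nperseg)
  mult <- rep(2, nf)
  mult[1] <- 1
  if (nperseg %% 2 == 0) mult[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd * mult)
}

# Lomb-Scargle periodogram on the irregular tachogram, rescaled to a
# one-sided density whose integral over the evaluated grid equals the
# sample variance of the detrended signal.
lomb_psd <- function(t, x, fmax, nfreq = 512L) {
  x <- x - mean(x)
  var_x <- mean(x^2)
  df <- fmax / nfreq
  freq <- seq(df, fmax, by = df)
  pwr <- vapply(freq, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2)) / 2
  }, numeric(1))
  total <- sum(pwr) * df
  scale <- if (total > 0) var_x / total else 0
  list(freq = freq, psd = pwr * scale)
}

#' Spectral band powers of an R-R series
#'
#' Estimates the power spectral density of the tachogram and integrates it
#' over the VLF, LF and HF bands. With the default Welch estimator the
#' irregularly spaced intervals are cubic-spline interpolated onto a uniform
#' grid first; the Lomb-Scargle estimator works on the beat times directly.
#' Powers are in ms^2.
#'
#' Bands whose lowest frequency cannot complete at least two cycles within
#' the recording are flagged as unreliable in `attr(, "unreliable")` rather
#' than silently reported.
#'
#' @param series An [rr_series()], ideally cleaned and spanning the full
#'   analysis window.
#' @param config A [spectral_config()].
#' @return A list with `vlf_power`, `lf_power`, `hf_power` (ms^2) and a
#'   character attribute `unreliable` naming bands the recording is too
#'   short to support.
#' @examples
#' t <- cumsum(rep(0.8, 400))
#' rr <- rr_series(800 + 25 * sin(2 * pi * 0.25 * t))
#' spectral_powers(rr)  # power concentrates in the HF band
#' @export
spectral_powers <- function(series, config = spectral_config()) {
  stopifnot(is_rr_series(series), inherits(config, "spectral_config"))
  t <- series$cumulative_time
  x <- series$intervals
  duration <- t[length(t)] - t[1]
  if (duration <= 0 || length(x) < 8L)
    stop_hrv("invalid_input", "series too short for spectral analysis")

  if (config$detrend == "linear") {
    fit <- stats::lm.fit(cbind(1, t), x)
    x <- fit$residuals
  }

  if (config$estimator == "welch") {
    fs <- config$resample_rate
    grid <- seq(t[1], t[length(t)], by = 1 / fs)
    xi <- stats::spline(t, x, xout = grid, method = "fmm")$y
    est <- welch_psd(xi, fs)
  } else {
    est <- lomb_psd(t, x, fmax = config$hf_band[2] * 1.25)
  }

  band_power <- function(band) {
    sel <- est$freq >= band[1] & est$freq < band[2]
    if (!any(sel)) return(0)
    df <- diff(est$freq[1:2])
    sum(est$psd[sel]) * df
  }
  unreliable <- character(0)
  for (nm in c("vlf", "lf", "hf")) {
    band <- config[[paste0(nm, "_band")]]
    if (duration < 2 / band[1]) unreliable <- c(unreliable, toupper(nm))
  }
  structure(
    list(vlf_power = band_power(config$vlf_band),
         lf_power = band_power(config$lf_band),
         hf_power = band_power(config$hf_band)),
    unreliable = unreliable
  )
}
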