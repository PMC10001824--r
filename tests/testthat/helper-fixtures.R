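# Fixtures are built in code: no stored data files.

# Tachogram with a pure sinusoidal modulation of the R-R interval.
sine_tachogram <- function(freq_hz, amp_ms = 25, mean_ms = 800,
                           n_beats = 500) {
  t <- cumsum(rep(mean_ms / 1000, n_beats))
  rr_series(mean_ms + amp_ms * sin(2 * pi * freq_hz * t))
}

# Literal transcription of the defining time-domain formulas, used as the
# independent brute-force oracle for small series.
oracle_time_domain <- function(x) {
  n <- length(x)
  sq <- 0
  for (i in seq_len(n - 1)) sq <- sq + (x[i + 1] - x[i])^2
  m <- sum(x) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (x[i] - m)^2
  list(mean_rr = m, rmssd = sqrt(sq / (n - 1)), sdnn = sqrt(ss / (n - 1)))
}

# Brute-force Baevsky SI from an explicit histogram.
oracle_baevsky <- function(x, bin_width_ms = 50) {
  lo <- floor(min(x) / bin_width_ms) * bin_width_ms
  hi <- ceiling(max(x) / bin_width_ms) * bin_width_ms
  edges <- seq(lo, hi, by = bin_width_ms)
  counts <- integer(length(edges) - 1)
  for (v in x) {
    for (j in seq_along(counts)) {
      if (v >= edges[j] && v < edges[j + 1]) counts[j] <- counts[j] + 1L
    }
  }
  k <- which.max(counts)
  mo_s <- (edges[k] + bin_width_ms / 2) / 1000
  amo <- 100 * counts[k] / length(x)
  mxdmn_s <- (max(x) - min(x)) / 1000
  amo / (2 * mo_s * mxdmn_s)
}

# Paired bivariate-normal sample with a known population CCC (equal means
# and variances, so population CCC = the shared correlation).
paired_with_ccc <- function(n, ccc, mean = 0, sd = 1) {
  b <- rnorm(n, 0, sd * sqrt(ccc))
  w <- sd * sqrt(1 - ccc)
  list(x = mean + b + rnorm(n, 0, w), y = mean + b + rnorm(n, 0, w))
}
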