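#' Lin's concordance correlation coefficient (point estimate)
#'
#' `CCC = 2 * cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, using
#' population (1/n) moments as in Lin's original definition. Combines
#' precision (correlation) with accuracy (penalty for mean and variance
#' disagreement), so |CCC| <= |Pearson r| always.
#'
#' @param x,y Paired measurement vectors of equal length >= 3.
#' @return The CCC, in \[-1, 1\].
#' @examples
#' lin_ccc_point(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
lin_ccc_point <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_hrv("invalid_input", "x and y must be paired vectors of length >= 3")
  if (anyNA(x) || anyNA(y))
    stop_hrv("invalid_input", "pairs must be complete (no missing values)")
  n <- length(x)
  vx <- mean((x - mean(x))^2)
  vy <- mean((y - mean(y))^2)
  if (vx == 0 && vy == 0)
    stop_hrv("undefined_concordance",
             "both measurement vectors are constant; CCC undefined")
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  2 * cxy / (vx + vy + (mean(x) - mean(y))^2)
}

#' Bayesian Lin's concordance correlation coefficient
#'
#' Posterior of the CCC induced by the posterior of a bivariate normal
#' model for the measurement pairs, under a vague conjugate
#' normal-inverse-Wishart prior (prior mean at the sample mean with prior
#' weight `kappa0 = 0.01`, `nu0 = 4` degrees of freedom, prior scale matrix
#' `diag` of the sample variances). Each posterior draw of `(mu, Sigma)` is
#' transformed to a CCC draw; the posterior median and 95% highest-density
#' interval are reported, with the agreement label on the median.
#'
#' @param x,y Paired measurement vectors of equal length >= 4.
#' @param n_draws Number of posterior draws (default 4000).
#' @param seed Integer seed for reproducibility.
#' @return A `concordance_result` list: `ccc_median`, `ci_low`, `ci_high`,
#'   `label`, `n`, `draws`.
#' @export
bayesian_ccc <- function(x, y, n_draws = 4000L, seed = 1L) {
  if (length(x) != length(y) || length(x) < 4L)
    stop_hrv("invalid_input", "x and y must be paired vectors of length >= 4")
  if (anyNA(x) || anyNA(y))
    stop_hrv("invalid_input", "pairs must be complete (no missing values)")
  n <- length(x)
  dat <- cbind(x, y)
  xbar <- colMeans(dat)
  S <- crossprod(sweep(dat, 2, xbar))       # sum of squares about the mean
  if (any(diag(S) == 0))
    stop_hrv("degenerate_covariance",
             "a measurement vector is constant; bivariate model degenerate")

  kappa0 <- 0.01
  nu0 <- 4                                   # dim + 2: vague but proper
  m0 <- xbar
  L0 <- diag(diag(S) / n)                    # scale: sample variances
  kappan <- kappa0 + n
  nun <- nu0 + n
  mn <- (kappa0 * m0 + n * xbar) / kappan
  dev <- xbar - m0
  Ln <- L0 + S + (kappa0 * n / kappan) * tcrossprod(dev)

  set.seed(seed)
  # Sigma ~ inverse-Wishart(nun, Ln): invert Wishart(nun, Ln^-1) draws
  W <- stats::rWishart(n_draws, nun, solve(Ln))
  ccc <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    Sig <- solve(W[, , i])
    mu <- mn + drop(chol(Sig / kappan) %*% stats::rnorm(2))
    ccc[i] <- 2 * Sig[1, 2] / (Sig[1, 1] + Sig[2, 2] + (mu[1] - mu[2])^2)
  }
  ci <- hdi(ccc, 0.95)
  med <- stats::median(ccc)
  structure(list(ccc_median = med, ci_low = ci[1], ci_high = ci[2],
                 label = classify_ccc(med), n = n, draws = ccc),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> CCC %.3f (%s), 95%% CrI [%.3f, %.3f], n = %d\n",
              x$ccc_median, x$label, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Label a concordance coefficient on the Evans scale
#'
#' CCC below 0.2, Very weak; 0.2 to below 0.4, Weak; 0.4 to below 0.6,
#' Moderate; 0.6 to below 0.8, Strong; 0.8 and above, Very strong.
#'
#' @param ccc A concordance value in \[-1, 1\].
#' @return Character label.
#' @examples
#' classify_ccc(0.722)  # "Strong"
#' @export
classify_ccc <- function(ccc) {
  if (is.na(ccc) || ccc < -1 || ccc > 1)
    stop_hrv("invalid_input", "CCC must lie in [-1, 1]")
  if (ccc < 0.2) "Very weak"
  else if (ccc < 0.4) "Weak"
  else if (ccc < 0.6) "Moderate"
  else if (ccc < 0.8) "Strong"
  else "Very strong"
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of y - x) and the 95% limits of agreement
#' (bias +/- 1.96 * sample SD of the differences), with the per-pair means
#' and differences exposed as plotting coordinates.
#'
#' @param x,y Paired measurement vectors of equal length >= 3.
#' @return A `bland_altman_result` list: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff` and a `points` data frame (`mean`, `diff`).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_hrv("invalid_input", "x and y must be paired vectors of length >= 3")
  if (anyNA(x) || anyNA(y))
    stop_hrv("invalid_input", "pairs must be complete (no missing values)")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s,
                 points = data.frame(mean = (x + y) / 2, diff = d)),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman_result> bias %.3f, 95%% LoA [%.3f, %.3f]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}
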