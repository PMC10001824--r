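#' Zero-centred Gaussian prior scaled to the response
#'
#' Builds the prior for the intercept of the between-session difference
#' model: Gaussian, centred at zero (the no-change expectation of a
#' test-retest design), with scale 2.5 times the standard deviation of the
#' response.
#'
#' @param response Numeric vector of response values (the per-subject
#'   session-2 minus session-1 differences).
#' @param multiplier Scale multiplier (default 2.5).
#' @return A `prior_spec` list with `location` (0), `scale` and `family`.
#' @export
build_prior <- function(response, multiplier = 2.5) {
  s <- stats::sd(response)
  if (!is.finite(s) || s <= 0)
    stop_hrv("configuration",
             "response has zero variance; cannot scale the prior")
  structure(list(location = 0, scale = multiplier * s, family = "gaussian"),
            class = "prior_spec")
}

#' MCMC settings for the difference models
#'
#' Defaults are a test-scale configuration (4 chains of 5,000 iterations,
#' half warm-up) that keeps full analyses fast while passing the usual
#' convergence gates; replication-scale runs (e.g. 5 chains of 50,000
#' with 25,000 warm-up) are available by argument.
#'
#' @param chains Number of chains (at least 2).
#' @param iterations Iterations per chain, including warm-up.
#' @param warmup Warm-up (discarded) iterations per chain.
#' @param seed Integer seed; every fit is reproducible given the seed.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 4L, iterations = 5000L,
                        warmup = floor(iterations / 2), seed = 1L) {
  if (chains < 2L)
    stop_hrv("unsupported_configuration",
             "at least 2 chains are required for convergence diagnostics")
  if (warmup >= iterations)
    stop_hrv("configuration", "warmup must be smaller than iterations")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Fit the intercept-only Gaussian model by Gibbs sampling
#'
#' Model: `y ~ Normal(mu, sigma)` with `mu ~ Normal(0, prior$scale)` and a
#' half-Student-t(3, 0, prior$scale) prior on `sigma`. The half-t prior is
#' represented as a scale mixture of inverse-gammas, which makes every full
#' conditional standard and the sampler a blocked Gibbs scheme:
#' `mu | sigma^2` is conjugate normal, `sigma^2 | mu, a` inverse-gamma, and
#' the mixing variable `a` inverse-gamma.
#'
#' @param y Numeric response (at least 5 values).
#' @param prior A `prior_spec` from [build_prior()].
#' @param mcmc An [mcmc_config()].
#' @return A `posterior_draws` object: list with `mu` and `sigma` matrices
#'   (post-warm-up iterations x chains), plus the prior, config and data
#'   summaries used.
#' @export
fit_intercept_model <- function(y, prior, mcmc = mcmc_config()) {
  stopifnot(inherits(prior, "prior_spec"), inherits(mcmc, "mcmc_config"))
  n <- length(y)
  if (n < 5L)
    stop_hrv("invalid_input", "intercept model needs at least 5 values, got %d", n)
  if (anyNA(y) || any(!is.finite(y)))
    stop_hrv("invalid_input", "response contains non-finite values")

  s0sq <- prior$scale^2       # prior variance of mu
  nu <- 3                     # half-t df for sigma
  A2 <- prior$scale^2         # half-t scale, squared
  ybar <- mean(y)
  keep <- mcmc$iterations - mcmc$warmup
  mu_draws <- matrix(NA_real_, keep, mcmc$chains)
  sg_draws <- matrix(NA_real_, keep, mcmc$chains)

  set.seed(mcmc$seed)
  for (ch in seq_len(mcmc$chains)) {
    # overdispersed chain starts around the sample statistics
    mu <- ybar + stats::rnorm(1, 0, stats::sd(y) / sqrt(n) * 3)
    sig2 <- stats::var(y) * exp(stats::rnorm(1, 0, 0.5))
    a <- 1
    for (it in seq_len(mcmc$iterations)) {
      # mu | sigma^2: conjugate normal
      prec <- n / sig2 + 1 / s0sq
      mu <- stats::rnorm(1, (n * ybar / sig2) / prec, sqrt(1 / prec))
      # a | sigma^2: inverse-gamma mixing variable of the half-t
      a <- 1 / stats::rgamma(1, (nu + 1) / 2, nu / sig2 + 1 / A2)
      # sigma^2 | mu, a: inverse-gamma
      rss <- sum((y - mu)^2)
      sig2 <- 1 / stats::rgamma(1, (n + nu) / 2, rss / 2 + nu / a)
      if (it > mcmc$warmup) {
        mu_draws[it - mcmc$warmup, ch] <- mu
        sg_draws[it - mcmc$warmup, ch] <- sqrt(sig2)
      }
    }
  }
  structure(list(mu = mu_draws, sigma = sg_draws, prior = prior,
                 config = mcmc, n = n, ybar = ybar, sd_y = stats::sd(y)),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d chains x %d draws; mu median %.4g\n",
              ncol(x$mu), nrow(x$mu), stats::median(x$mu)))
  invisible(x)
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing `prob` of the draws (assumes a unimodal
#' posterior, as holds for this model family).
#'
#' @param draws Numeric vector of posterior draws.
#' @param prob Interval mass (default 0.95).
#' @return `c(lower, upper)`.
#' @export
hdi <- function(draws, prob = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(prob * n)
  if (m >= n) return(c(x[1], x[n]))
  # window of m consecutive order statistics with the smallest width
  i <- which.min(x[m:n] - x[1:(n - m + 1)])
  c(x[i], x[i + m - 1])
}

#' Probability of direction
#'
#' The posterior probability that the effect is strictly positive or
#' strictly negative, whichever is larger; draws exactly at zero count
#' toward neither sign.
#'
#' @param draws Numeric vector of posterior draws of the effect.
#' @return A value in \[0.5, 1\] (0.5 by convention when no draw has a sign).
#' @export
probability_of_direction <- function(draws) {
  pos <- sum(draws > 0)
  neg <- sum(draws < 0)
  if (pos + neg == 0) return(0.5)
  max(pos, neg) / (pos + neg)
}

#' Region of practical equivalence occupancy
#'
#' The ROPE is the symmetric region `c(-0.1, 0.1) * response_sd` around
#' zero; occupancy is the percentage of the full posterior sample falling
#' inside it (not the HDI-restricted variant).
#'
#' @param draws Posterior draws of the effect.
#' @param response_sd Standard deviation of the response variable.
#' @param multiplier Half-width of the ROPE as a fraction of `response_sd`
#'   (default 0.1).
#' @return A list with `rope_low`, `rope_high` and `pct_inside` (0-100).
#' @export
rope_percentage <- function(draws, response_sd, multiplier = 0.1) {
  if (!is.finite(response_sd) || response_sd <= 0)
    stop_hrv("configuration", "response_sd must be positive")
  half <- multiplier * response_sd
  list(rope_low = -half, rope_high = half,
       pct_inside = 100 * mean(draws >= -half & draws <= half))
}

#' Savage-Dickey Bayes factor against the point null
#'
#' `BF10 = prior density at 0 / posterior density at 0`; values above 1
#' favour a non-zero effect, below 1 the null. The posterior density at
#' zero is evaluated from a normal approximation to the posterior draws
#' (the posterior of the intercept is very close to normal in this model),
#' or by Gaussian kernel density estimation.
#'
#' @param draws Posterior draws of the effect.
#' @param prior A `prior_spec`.
#' @param method `"analytic"` (moment-matched normal, default) or `"kde"`.
#' @return The Bayes factor BF10 (> 0; `Inf` with a warning if the
#'   posterior density at zero underflows).
#' @export
savage_dickey_bf10 <- function(draws, prior, method = c("analytic", "kde")) {
  method <- match.arg(method)
  stopifnot(inherits(prior, "prior_spec"))
  prior_d0 <- stats::dnorm(0, prior$location, prior$scale)
  post_d0 <- if (method == "analytic") {
    stats::dnorm(0, mean(draws), stats::sd(draws))
  } else {
    d <- stats::density(draws)
    stats::approx(d$x, d$y, xout = 0, yleft = 0, yright = 0)$y
  }
  if (is.infinite(post_d0)) return(0)  # point mass at the null value
  if (is.na(post_d0) || post_d0 <= 0) {
    warn_hrv("bf_overflow",
             "posterior density at 0 is numerically zero; BF10 reported as Inf")
    return(Inf)
  }
  prior_d0 / post_d0
}

#' Interpret a Bayes factor on the conventional evidence scale
#'
#' BF10 below 1 is evidence for the null; it is classified by the magnitude
#' of its reciprocal and tagged as favouring the null. The scale:
#' 1, none; (1, 3\], anecdotal; (3, 10\], moderate; (10, 30\], strong;
#' (30, 100\], very strong; above 100, extreme.
#'
#' @param bf Bayes factor BF10 (> 0).
#' @return A list with `magnitude` (evidence strength label), `direction`
#'   (`"against null"`, `"in favor of null"` or `"none"`) and `label`
#'   (the two pasted together).
#' @examples
#' classify_bf(5)     # moderate evidence against the null
#' classify_bf(0.05)  # reciprocal 20: strong evidence in favor of the null
#' @export
classify_bf <- function(bf) {
  if (is.na(bf) || bf < 0)
    stop_hrv("invalid_input", "Bayes factor must be non-negative")
  if (bf == 1)
    return(list(magnitude = "no evidence", direction = "none",
                label = "no evidence"))
  # 0 and Inf are the degenerate limits of overwhelming evidence
  if (bf == 0)
    return(list(magnitude = "extreme", direction = "in favor of null",
                label = "extreme in favor of null"))
  direction <- if (bf > 1) "against null" else "in favor of null"
  b <- if (bf > 1) bf else 1 / bf
  magnitude <-
    if (b <= 3) "anecdotal"
    else if (b <= 10) "moderate"
    else if (b <= 30) "strong"
    else if (b <= 100) "very strong"
    else "extreme"
  list(magnitude = magnitude, direction = direction,
       label = paste(magnitude, direction))
}

#' Interpret ROPE occupancy as practical significance
#'
#' Scale applied to the percentage of the posterior inside the ROPE:
#' below 1%, significant; below 2.5%, probably significant; between 2.5%
#' and 97.5% inclusive, undecided significance; above 97.5%, probably
#' negligible; above 99%, negligible.
#'
#' @param pct_inside Percentage in \[0, 100\].
#' @return Character label.
#' @export
classify_rope <- function(pct_inside) {
  if (is.na(pct_inside) || pct_inside < 0 || pct_inside > 100)
    stop_hrv("invalid_input", "pct_inside must be between 0 and 100")
  if (pct_inside < 1) "significant"
  else if (pct_inside < 2.5) "probably significant"
  else if (pct_inside <= 97.5) "undecided significance"
  else if (pct_inside > 99) "negligible"
  else "probably negligible"
}

#' Convergence diagnostics for posterior draws
#'
#' Split R-hat (each chain halved, the potential scale reduction factor
#' computed over the 2 x chains half-chains) and the effective sample size
#' (via `coda`, summed across chains) for both model parameters. The run
#' passes when every R-hat is below 1.01 and every ESS above 1000.
#'
#' @param draws A `posterior_draws` object, or a draws matrix
#'   (iterations x chains) for a single parameter.
#' @return A `mcmc_diagnostics` list: `rhat`, `ess` (named per parameter)
#'   and `pass`.
#' @export
diagnostics <- function(draws) {
  mats <- if (inherits(draws, "posterior_draws")) {
    list(mu = draws$mu, sigma = draws$sigma)
  } else {
    list(par = as.matrix(draws))
  }
  if (ncol(mats[[1]]) < 2L)
    stop_hrv("unsupported_configuration",
             "diagnostics require at least 2 chains")
  rhat <- vapply(mats, split_rhat, numeric(1))
  ess <- vapply(mats, function(m) {
    if (stats::var(as.vector(m)) == 0) return(0)  # degenerate chain
    ml <- coda::mcmc.list(lapply(seq_len(ncol(m)), function(j) coda::mcmc(m[, j])))
    as.numeric(coda::effectiveSize(ml))
  }, numeric(1))
  structure(list(rhat = rhat, ess = ess,
                 pass = all(rhat < 1.01) && all(ess > 1000)),
            class = "mcmc_diagnostics")
}

split_rhat <- function(m) {
  niter <- nrow(m)
  half <- floor(niter / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) {
    cbind(m[1:half, j], m[(niter - half + 1):niter, j])
  }))
  n <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' SEXIT-style posterior summary of a difference model
#'
#' Assembles the full sequential-effect-existence-and-significance
#' description of one between-session difference model: posterior median
#' and 95% highest-density interval (centrality and uncertainty),
#' probability of direction (existence), ROPE bounds and occupancy with its
#' label (practical significance), the Savage-Dickey Bayes factor with its
#' evidence label (absolute evidence), and the convergence diagnostics.
#'
#' @param draws A `posterior_draws` object from [fit_intercept_model()].
#' @param response_sd SD of the response used for the ROPE; defaults to the
#'   SD stored with the draws.
#' @param rope_multiplier ROPE half-width as a fraction of `response_sd`.
#' @param bf_method Passed to [savage_dickey_bf10()].
#' @return A `posterior_summary` list with fields `median`, `hdi_low`,
#'   `hdi_high`, `pd`, `rope_low`, `rope_high`, `rope_pct_inside`,
#'   `rope_label`, `bf10`, `bf_label`, `rhat`, `ess` and `pass`.
#' @export
sexit_summary <- function(draws, response_sd = NULL, rope_multiplier = 0.1,
                          bf_method = "analytic") {
  stopifnot(inherits(draws, "posterior_draws"))
  if (is.null(response_sd)) response_sd <- draws$sd_y
  mu <- as.vector(draws$mu)
  diag <- diagnostics(draws)
  ci <- hdi(mu, 0.95)
  rope <- rope_percentage(mu, response_sd, rope_multiplier)
  bf <- savage_dickey_bf10(mu, draws$prior, method = bf_method)
  structure(list(
    median = stats::median(mu),
    hdi_low = ci[1], hdi_high = ci[2],
    pd = probability_of_direction(mu),
    rope_low = rope$rope_low, rope_high = rope$rope_high,
    rope_pct_inside = rope$pct_inside,
    rope_label = classify_rope(rope$pct_inside),
    bf10 = bf,
    bf_label = classify_bf(bf)$label,
    rhat = max(diag$rhat), ess = min(diag$ess),
    pass = diag$pass
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<posterior_summary> median %.3f, 95%% HDI [%.3f, %.3f], ",
           "pd %.1f%%, ROPE %.1f%% (%s), BF10 %.3f (%s)%s\n"),
    x$median, x$hdi_low, x$hdi_high, 100 * x$pd, x$rope_pct_inside,
    x$rope_label, x$bf10, x$bf_label,
    if (!x$pass) " [diagnostics FAILED]" else ""))
  invisible(x)
}
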