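make_draws <- function(mu_mat, sigma_mat = NULL, prior_scale = 10, sd_y = 1) {
  # assemble a posterior_draws object around injected draws
  if (is.null(sigma_mat)) sigma_mat <- abs(mu_mat) + 1
  structure(list(mu = mu_mat, sigma = sigma_mat,
                 prior = structure(list(location = 0, scale = prior_scale,
                                        family = "gaussian"),
                                   class = "prior_spec"),
                 config = mcmc_config(chains = ncol(mu_mat),
                                      iterations = 2L * nrow(mu_mat),
                                      warmup = nrow(mu_mat)),
                 n = 100L, ybar = mean(mu_mat), sd_y = sd_y),
            class = "posterior_draws")
}

test_that("the prior is zero-centred and scaled to the response", {
  y <- c(-2, 0, 2, -2, 2)                  # sd = 2
  p <- build_prior(y)
  expect_equal(p$location, 0)
  expect_equal(p$scale, 2.5 * sd(y))
  z <- rnorm(50)
  expect_equal(build_prior(z)$scale, 2.5 * sd(z))
  expect_error(build_prior(rep(3, 10)), class = "hrv_configuration")
})

test_that("the Gibbs sampler matches the conjugate closed form", {
  set.seed(12)
  y <- rnorm(200)
  prior <- build_prior(y)
  fit <- fit_intercept_model(y, prior, mcmc_config(seed = 5L))
  # conjugate posterior of mu with sigma fixed at sd(y)
  n <- length(y); s2 <- var(y)
  post_var <- 1 / (n / s2 + 1 / prior$scale^2)
  post_mean <- post_var * n * mean(y) / s2
  ess <- diagnostics(fit)$ess["mu"]
  mcse <- sd(fit$mu) / sqrt(ess)
  expect_lt(abs(mean(fit$mu) - post_mean), 3 * mcse)
  expect_equal(sd(fit$mu), sqrt(post_var), tolerance = 0.05)
})

test_that("a nearly flat prior recovers the sample mean", {
  set.seed(13)
  y <- rnorm(100, 5, 2)
  wide <- structure(list(location = 0, scale = 1e6, family = "gaussian"),
                    class = "prior_spec")
  fit <- fit_intercept_model(y, wide, mcmc_config(seed = 2L))
  expect_equal(mean(fit$mu), mean(y), tolerance = 0.05)
})

test_that("fits are reproducible by seed and error on bad input", {
  y <- rnorm(30)
  p <- build_prior(y)
  f1 <- fit_intercept_model(y, p, mcmc_config(iterations = 1000L, seed = 9L))
  f2 <- fit_intercept_model(y, p, mcmc_config(iterations = 1000L, seed = 9L))
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$sigma, f2$sigma)
  f3 <- fit_intercept_model(y, p, mcmc_config(iterations = 1000L, seed = 10L))
  expect_false(identical(f1$mu, f3$mu))

  expect_error(fit_intercept_model(rnorm(4), p), class = "hrv_invalid_input")
  expect_error(mcmc_config(chains = 1L), class = "hrv_unsupported_configuration")
  expect_error(mcmc_config(iterations = 100L, warmup = 100L),
               class = "hrv_configuration")
})

test_that("probability of direction counts signed draws", {
  expect_equal(probability_of_direction(c(-2, -1, 1, 2)), 0.5)
  expect_equal(probability_of_direction(c(1, 2, 3)), 1)
  expect_equal(probability_of_direction(rep(0, 100)), 0.5)
  # ties at zero join neither side
  expect_equal(probability_of_direction(c(0, 0, 1, 1, -1)), 2 / 3)
  set.seed(3)
  draws <- rnorm(2e5, 1, 0.5)
  expect_equal(probability_of_direction(draws), pnorm(2), tolerance = 0.005)
})

test_that("ROPE occupancy matches the normal CDF oracle", {
  set.seed(4)
  draws <- rnorm(2e5, 0, 1)
  r <- rope_percentage(draws, response_sd = 1)
  expect_equal(r$rope_low, -0.1)
  expect_equal(r$rope_high, 0.1)
  expect_equal(r$pct_inside, 100 * (2 * pnorm(0.1) - 1), tolerance = 0.5)

  expect_equal(rope_percentage(rep(0, 100), 1)$pct_inside, 100)
  expect_equal(rope_percentage(rnorm(100, 50, 0.1), 1)$pct_inside, 0)
  expect_error(rope_percentage(draws, 0), class = "hrv_configuration")
})

test_that("Savage-Dickey ratio reproduces normal-density arithmetic", {
  prior <- structure(list(location = 0, scale = 10, family = "gaussian"),
                     class = "prior_spec")
  set.seed(5)
  # posterior identical to the prior: BF10 = 1
  self <- rnorm(2e5, 0, 10)
  expect_equal(savage_dickey_bf10(self, prior), 1, tolerance = 0.02)
  # posterior N(0, 1) against prior N(0, 10): BF10 = 0.1
  post <- rnorm(2e5, 0, 1)
  expect_equal(savage_dickey_bf10(post, prior), 0.1, tolerance = 0.005)
  expect_equal(savage_dickey_bf10(post, prior, method = "kde"), 0.1,
               tolerance = 0.05)
  # a posterior far from zero overwhelms the null
  far <- rnorm(1e4, 8, 0.5)
  expect_gt(savage_dickey_bf10(far, prior), 100)
})

test_that("Bayes factor labels follow the printed evidence scale", {
  expect_equal(classify_bf(1)$label, "no evidence")
  expect_equal(classify_bf(2)$label, "anecdotal against null")
  expect_equal(classify_bf(3)$magnitude, "anecdotal")
  expect_equal(classify_bf(3 + 1e-9)$magnitude, "moderate")
  expect_equal(classify_bf(5)$label, "moderate against null")
  expect_equal(classify_bf(10)$magnitude, "moderate")
  expect_equal(classify_bf(10.001)$magnitude, "strong")
  expect_equal(classify_bf(30)$magnitude, "strong")
  expect_equal(classify_bf(30.001)$magnitude, "very strong")
  expect_equal(classify_bf(100)$magnitude, "very strong")
  expect_equal(classify_bf(101)$magnitude, "extreme")
  # reciprocal symmetry: same magnitude, opposite direction
  for (b in c(1.5, 4, 15, 60, 500)) {
    up <- classify_bf(b); down <- classify_bf(1 / b)
    expect_equal(up$magnitude, down$magnitude)
    expect_equal(up$direction, "against null")
    expect_equal(down$direction, "in favor of null")
  }
  expect_equal(classify_bf(0.05)$label, "strong in favor of null")
  expect_error(classify_bf(-1), class = "hrv_invalid_input")
})

test_that("ROPE labels follow the printed significance scale", {
  expect_equal(classify_rope(0.3), "significant")
  expect_equal(classify_rope(0.999), "significant")
  expect_equal(classify_rope(1), "probably significant")
  expect_equal(classify_rope(2.4), "probably significant")
  expect_equal(classify_rope(2.5), "undecided significance")
  expect_equal(classify_rope(50), "undecided significance")
  expect_equal(classify_rope(97.5), "undecided significance")
  expect_equal(classify_rope(97.6), "probably negligible")
  expect_equal(classify_rope(99), "probably negligible")
  expect_equal(classify_rope(99.5), "negligible")
  expect_error(classify_rope(101), class = "hrv_invalid_input")
})

test_that("convergence diagnostics separate mixed from unmixed chains", {
  set.seed(6)
  good <- matrix(rnorm(4000), 1000, 4)
  d <- diagnostics(make_draws(good))
  expect_lt(max(d$rhat), 1.01)
  expect_true(d$pass)
  # independent draws: ESS close to the total draw count
  expect_gt(min(d$ess), 0.8 * 4000)

  bad <- cbind(rnorm(1000, 0), rnorm(1000, 5), rnorm(1000, 0), rnorm(1000, 5))
  db <- diagnostics(make_draws(bad))
  expect_gt(max(db$rhat), 1.01)
  expect_false(db$pass)

  expect_error(diagnostics(matrix(rnorm(100), 100, 1)),
               class = "hrv_unsupported_configuration")
})

test_that("the HDI is never wider than the equal-tailed interval", {
  set.seed(8)
  for (rep in 1:20) {
    draws <- rgamma(5000, shape = runif(1, 1, 6)) * sample(c(-1, 1), 1)
    h <- hdi(draws, 0.95)
    q <- quantile(draws, c(0.025, 0.975), names = FALSE)
    expect_lte(h[2] - h[1], q[2] - q[1] + 1e-12)
  }
})

test_that("the SEXIT summary matches closed forms on an injected posterior", {
  set.seed(10)
  m <- 0.8; s <- 0.4
  mu <- matrix(rnorm(40000, m, s), 10000, 4)
  draws <- make_draws(mu, matrix(abs(rnorm(40000, 1, 0.1)), 10000, 4),
                      prior_scale = 2.5, sd_y = 1)
  sx <- sexit_summary(draws)
  expect_equal(sx$median, m, tolerance = 0.02)
  expect_equal(sx$pd, pnorm(m / s), tolerance = 0.01)
  expect_equal(sx$hdi_low, m - 1.96 * s, tolerance = 0.03)
  expect_equal(sx$hdi_high, m + 1.96 * s, tolerance = 0.03)
  expect_equal(sx$rope_low, -0.1)
  expect_equal(sx$rope_pct_inside,
               100 * (pnorm((0.1 - m) / s) - pnorm((-0.1 - m) / s)),
               tolerance = 0.5)
  bf_expected <- dnorm(0, 0, 2.5) / dnorm(0, m, s)
  expect_equal(sx$bf10, bf_expected, tolerance = 0.1 * bf_expected)
  expect_true(sx$pass)

  # degenerate posterior: everything collapses to the null point
  zero <- make_draws(matrix(0, 2000, 2), matrix(1, 2000, 2))
  sz <- sexit_summary(zero)
  expect_equal(sz$median, 0)
  expect_equal(sz$pd, 0.5)
  expect_equal(sz$rope_pct_inside, 100)
  expect_false(sz$pass)  # zero-variance chains cannot pass the ESS gate
})
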