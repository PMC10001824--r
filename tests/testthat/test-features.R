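test_that("time-domain indices match the brute-force oracle on small series", {
  x <- c(800, 810, 790, 805, 795)
  td <- time_domain(rr_series(x))
  oracle <- oracle_time_domain(x)
  expect_equal(td$mean_rr, oracle$mean_rr, tolerance = 1e-12)
  expect_equal(td$rmssd, oracle$rmssd, tolerance = 1e-12)
  expect_equal(td$sdnn, oracle$sdnn, tolerance = 1e-12)
  # the hand computation for this exact series
  expect_equal(td$rmssd, sqrt(206.25), tolerance = 1e-12)
  expect_equal(td$mean_rr, 800)
  expect_equal(td$sdnn, sqrt(250 / 4), tolerance = 1e-12)

  set.seed(42)
  for (rep in 1:10) {
    y <- runif(sample(3:10, 1), 600, 1100)
    td <- time_domain(rr_series(y))
    oracle <- oracle_time_domain(y)
    expect_equal(td$rmssd, oracle$rmssd, tolerance = 1e-9)
    expect_equal(td$sdnn, oracle$sdnn, tolerance = 1e-9)
  }
})

test_that("degenerate and identity cases of the time domain hold", {
  td <- time_domain(rr_series(rep(750, 50)))
  expect_equal(td$rmssd, 0)
  expect_equal(td$sdnn, 0)
  expect_equal(td$hr_mean, 60000 / 750)
  expect_error(time_domain(rr_series(c(800, 810))), class = "hrv_invalid_input")
})

test_that("SD1 equals RMSSD / sqrt(2) on any series", {
  set.seed(7)
  for (rep in 1:20) {
    x <- runif(sample(3:200, 1), 500, 1200)
    rr <- rr_series(x)
    expect_equal(poincare(rr)$sd1, time_domain(rr)$rmssd / sqrt(2),
                 tolerance = 1e-9)
  }
})

test_that("Poincare axes behave as rotated-scatter spreads", {
  expect_equal(poincare(rr_series(rep(800, 20))), list(sd1 = 0, sd2 = 0))
  # alternation is pure short-axis variability
  alt <- rr_series(rep(c(790, 810), 50))
  pc <- poincare(alt)
  expect_gt(pc$sd1, 5)
  expect_lt(pc$sd2, 1e-9)
})

test_that("time-domain and Poincare indices scale linearly with the beats", {
  set.seed(3)
  x <- runif(100, 700, 900)
  for (c_scale in c(0.5, 2, 3.7)) {
    a <- c(time_domain(rr_series(x))[c("mean_rr", "rmssd", "sdnn")],
           poincare(rr_series(x)))
    b <- c(time_domain(rr_series(c_scale * x))[c("mean_rr", "rmssd", "sdnn")],
           poincare(rr_series(c_scale * x)))
    expect_equal(unlist(b), c_scale * unlist(a), tolerance = 1e-9)
  }
})

test_that("Baevsky SI matches the histogram oracle and is monotone in spread", {
  set.seed(9)
  x <- runif(100, 700, 900)
  expect_equal(baevsky_si(rr_series(x), 50), oracle_baevsky(x, 50),
               tolerance = 1e-12)

  expect_error(baevsky_si(rr_series(rep(800, 100))),
               class = "hrv_degenerate_distribution")

  # widening the range at a fixed modal bin strictly decreases SI
  base <- c(rep(810, 60), seq(700, 900, length.out = 40))
  wide <- c(rep(810, 60), seq(600, 1000, length.out = 40))
  expect_gt(baevsky_si(rr_series(base)), baevsky_si(rr_series(wide)))
})

test_that("composite autonomic indices are norm-relative z-score means", {
  norms <- norm_reference()
  at_norm <- list(mean_rr = norms$mean_rr[1], rmssd = norms$rmssd[1],
                  sd1 = norms$sd1[1], sd2 = norms$sd2[1],
                  baevsky_si = norms$baevsky_si[1])
  ai <- autonomic_indices(at_norm, norms)
  expect_equal(ai$pns_index, 0)
  expect_equal(ai$sns_index, 0)

  # one SD of mean RR above the norm moves PNS by +1/3 and SNS by -1/3
  up <- at_norm
  up$mean_rr <- norms$mean_rr[1] + norms$mean_rr[2]
  ai <- autonomic_indices(up, norms)
  expect_equal(ai$pns_index, 1 / 3, tolerance = 1e-12)
  expect_equal(ai$sns_index, -1 / 3, tolerance = 1e-12)

  # raising RMSSD strictly raises PNS; raising SI strictly raises SNS
  hi_rmssd <- at_norm; hi_rmssd$rmssd <- at_norm$rmssd + 10
  expect_gt(autonomic_indices(hi_rmssd, norms)$pns_index, ai$pns_index - 1)
  expect_gt(autonomic_indices(hi_rmssd, norms)$pns_index,
            autonomic_indices(at_norm, norms)$pns_index)
  hi_si <- at_norm; hi_si$baevsky_si <- at_norm$baevsky_si + 50
  expect_gt(autonomic_indices(hi_si, norms)$sns_index,
            autonomic_indices(at_norm, norms)$sns_index)

  incomplete <- at_norm; incomplete$sd2 <- NULL
  expect_error(autonomic_indices(incomplete, norms),
               class = "hrv_configuration")
})

test_that("%HRmax follows the age-predicted maximum formulas", {
  expect_equal(pct_hrmax(100, 70), 100 / 150 * 100, tolerance = 1e-12)
  expect_equal(pct_hrmax(150, 70), 100)
  expect_equal(pct_hrmax(100, 70, "tanaka"), 100 / (208 - 49) * 100,
               tolerance = 1e-12)
  expect_error(pct_hrmax(0, 70), class = "hrv_invalid_input")
  expect_error(pct_hrmax(100, 30), class = "hrv_invalid_input")
})

test_that("compute_all composes the stages deterministically", {
  rr <- generate_rr(rr_synth_config(duration_s = 600, seed = 21L))
  f1 <- compute_all(rr, age = 71)
  f2 <- compute_all(rr, age = 71)
  expect_identical(unclass(f1), unclass(f2))

  expect_gte(f1$rmssd, 0)
  expect_gte(f1$sdnn, 0)
  expect_gte(f1$hf_power, 0)
  expect_gte(f1$lf_power, 0)
  expect_gte(f1$vlf_power, 0)
  expect_equal(f1$sd1, f1$rmssd / sqrt(2), tolerance = 1e-9)
  expect_equal(f1$stress_index, sqrt(f1$baevsky_si), tolerance = 1e-12)
  expect_equal(f1$hr_mean, 60000 / f1$mean_rr, tolerance = 1e-12)
  expect_false(attr(f1, "cleaning")$exceeded_threshold)

  dirty <- generate_rr(rr_synth_config(duration_s = 600, ectopic_rate = 0.06,
                                       seed = 22L))
  fd <- compute_all(dirty, age = 71)
  expect_true(attr(fd, "cleaning")$exceeded_threshold)

  short <- generate_rr(rr_synth_config(duration_s = 120, seed = 23L))
  expect_error(compute_all(short, age = 71), class = "hrv_stage_failure")
})
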