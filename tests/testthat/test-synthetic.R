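test_that("generate_rr honours its configuration", {
  # no modulation, no noise: a constant series at the configured mean
  quiet <- rr_synth_config(duration_s = 60, hf_amp_ms = 0, lf_amp_ms = 0,
                           white_noise_sd_ms = 0, seed = 1L)
  rr <- generate_rr(quiet)
  expect_true(all(rr$intervals == 800))
  expect_gte(rr_duration(rr), 60)

  # HF-only modulation dominates the HF band (shared single-tone oracle)
  hf_only <- generate_rr(rr_synth_config(duration_s = 300, lf_amp_ms = 0,
                                         white_noise_sd_ms = 0, seed = 2L))
  sp <- spectral_powers(hf_only)
  expect_gt(sp$hf_power, sp$lf_power)
  expect_gt(sp$hf_power, sp$vlf_power)

  expect_identical(generate_rr(rr_synth_config(seed = 5L))$intervals,
                   generate_rr(rr_synth_config(seed = 5L))$intervals)
  expect_error(rr_synth_config(ectopic_rate = 0.5), class = "hrv_invalid_config")
  expect_error(rr_synth_config(hf_freq_hz = 0.05), class = "hrv_invalid_config")
  expect_error(generate_rr(rr_synth_config(white_noise_sd_ms = 500, seed = 3L)),
               class = "hrv_invalid_config")
})

test_that("injected ectopics are recovered by the cleaner at the binomial rate", {
  rate <- 0.05
  flagged <- vapply(1:8, function(s) {
    rr <- generate_rr(rr_synth_config(duration_s = 240, white_noise_sd_ms = 5,
                                      ectopic_rate = rate, seed = s))
    n <- length(rr$intervals)
    clean_rr(rr)$report$n_flagged / n
  }, numeric(1))
  n_typ <- 300
  tol <- 2 * sqrt(n_typ * rate * (1 - rate)) / n_typ
  expect_lt(abs(mean(flagged) - rate), tol)
})

test_that("the cohort generator reproduces its configured demography", {
  cfg <- cohort_synth_config(seed = 31L)
  ds <- generate_cohort(cfg)
  expect_equal(nrow(ds$subjects), 105)
  expect_equal(nrow(ds$grid), 105 * 4)
  expect_equal(nrow(ds$hr_exercise), 105 * 2)

  # age and sex match the configuration within sampling error
  expect_lt(abs(mean(ds$subjects$age) - 70.9), 3 * 5.9 / sqrt(105) + 0.5)
  expect_lt(abs(mean(ds$subjects$sex == "F") - 0.781),
            3 * sqrt(0.781 * 0.219 / 105))

  # byte-identical regeneration under the same seed
  expect_identical(generate_cohort(cfg), ds)
  # per-subject substreams: the first subjects do not depend on cohort size
  small <- generate_cohort(cohort_synth_config(n_subjects = 10L, seed = 31L))
  expect_identical(small$grid, ds$grid[ds$grid$subject_id %in%
                                         small$subjects$subject_id, ])
})

test_that("the within-subject SD solver hits the target concordance", {
  p <- default_index_params()
  # closed-form identity: ccc = tau^2 / (tau^2 + sigma_w^2 + shift^2/2)
  cfg <- cohort_synth_config(seed = 1L)
  with_sd <- cfg$index_params$within_sd
  implied <- cfg$index_params$between_sd^2 /
    (cfg$index_params$between_sd^2 + with_sd^2 +
       cfg$index_params$session_shift^2 / 2)
  expect_equal(implied, cfg$index_params$target_ccc, tolerance = 1e-9)

  bad <- p
  bad$target_ccc[1] <- 0.999
  bad$session_shift[1] <- bad$between_sd[1] * 2
  expect_error(cohort_synth_config(index_params = bad), class = "hrv_solver")
})

test_that("long-format conversion is complete, sized and lossless", {
  ds <- generate_cohort(cohort_synth_config(n_subjects = 12L, seed = 7L))
  long <- cohort_to_long(ds)
  expect_equal(nrow(long), 12 * 2 * 2 * 9)
  expect_setequal(unique(long$index_name), default_index_params()$index_name)

  grid2 <- long_to_grid(long)
  long2 <- cohort_to_long(grid2)
  expect_equal(long2, long)

  broken <- ds$grid[-3, ]  # drop one recording
  err <- expect_error(cohort_to_long(broken), class = "hrv_missing_cell")
  expect_match(conditionMessage(err), "S001")
})

test_that("cohort files round-trip through the writers", {
  dir <- withr::local_tempdir()
  ds <- generate_cohort(cohort_synth_config(n_subjects = 6L, seed = 3L))
  write_cohort(ds, dir)
  expect_true(all(file.exists(file.path(
    dir, c("subjects.csv", "measurements.csv", "hr_exercise.csv",
           "ground_truth.json")))))
  long <- read_measurements_csv(file.path(dir, "measurements.csv"))
  expect_equal(nrow(long), 6 * 4 * 9)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(gt$n_subjects, 6)
})
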