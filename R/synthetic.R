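#' Configuration for synthetic R-R tachograms
#'
#' Parameters of a simple additive tachogram model: a constant mean R-R
#' interval modulated by one high-frequency sinusoid (respiratory sinus
#' arrhythmia surrogate), one low-frequency sinusoid (baroreflex
#' surrogate), white beat-to-beat noise, and randomly placed ectopic-like
#' artifacts (isolated halved or doubled intervals).
#'
#' @param duration_s Recording length in seconds (default 600: a 10-minute
#'   rest recording from which the trailing 5 minutes are analysed).
#' @param mean_rr_ms Mean R-R interval (ms).
#' @param hf_amp_ms,hf_freq_hz High-frequency modulation amplitude (ms) and
#'   frequency (Hz, inside the 0.15-0.40 HF band).
#' @param lf_amp_ms,lf_freq_hz Low-frequency modulation amplitude (ms) and
#'   frequency (Hz, inside the 0.04-0.15 LF band).
#' @param white_noise_sd_ms SD of additive white noise (ms).
#' @param ectopic_rate Fraction of beats replaced by artifacts, in
#'   \[0, 0.2).
#' @param seed Integer seed.
#' @return An `rr_synth_config` list.
#' @export
rr_synth_config <- function(duration_s = 600, mean_rr_ms = 800,
                            hf_amp_ms = 25, hf_freq_hz = 0.25,
                            lf_amp_ms = 15, lf_freq_hz = 0.09,
                            white_noise_sd_ms = 10, ectopic_rate = 0,
                            seed = 1L) {
  if (hf_amp_ms < 0 || lf_amp_ms < 0 || white_noise_sd_ms < 0)
    stop_hrv("invalid_config", "amplitudes and noise SD must be non-negative")
  if (ectopic_rate < 0 || ectopic_rate >= 0.2)
    stop_hrv("invalid_config", "ectopic_rate must be in [0, 0.2)")
  if (hf_freq_hz < 0.15 || hf_freq_hz > 0.40)
    stop_hrv("invalid_config", "hf_freq_hz must lie in the HF band (0.15-0.40 Hz)")
  if (lf_freq_hz < 0.04 || lf_freq_hz > 0.15)
    stop_hrv("invalid_config", "lf_freq_hz must lie in the LF band (0.04-0.15 Hz)")
  if (duration_s <= 0 || mean_rr_ms <= 0)
    stop_hrv("invalid_config", "duration and mean RR must be positive")
  structure(as.list(environment()), class = "rr_synth_config")
}

#' Generate a synthetic R-R interval series
#'
#' Beats are laid down sequentially; each interval is the configured mean
#' plus the two sinusoidal modulations evaluated at the beat onset time
#' plus white noise. Artifacts are injected by halving or doubling isolated
#' intervals at the configured rate. Deterministic per seed.
#'
#' @param config An [rr_synth_config()].
#' @return An [rr_series()] spanning at least `duration_s` seconds.
#' @examples
#' rr <- generate_rr(rr_synth_config(duration_s = 120, seed = 42))
#' @export
generate_rr <- function(config = rr_synth_config()) {
  stopifnot(inherits(config, "rr_synth_config"))
  set.seed(config$seed)
  n_max <- ceiling(config$duration_s * 1000 / config$mean_rr_ms * 1.5) + 10L
  intervals <- numeric(n_max)
  t_ms <- 0
  n <- 0L
  while (t_ms < config$duration_s * 1000 && n < n_max) {
    ts <- t_ms / 1000
    rr <- config$mean_rr_ms +
      config$hf_amp_ms * sin(2 * pi * config$hf_freq_hz * ts) +
      config$lf_amp_ms * sin(2 * pi * config$lf_freq_hz * ts) +
      stats::rnorm(1, 0, config$white_noise_sd_ms)
    if (rr <= 0)
      stop_hrv("invalid_config",
               "configured amplitudes/noise produced a non-positive interval")
    n <- n + 1L
    intervals[n] <- rr
    t_ms <- t_ms + rr
  }
  intervals <- intervals[seq_len(n)]
  if (config$ectopic_rate > 0) {
    hit <- which(stats::runif(n) < config$ectopic_rate)
    if (length(hit)) {
      factor <- ifelse(stats::runif(length(hit)) < 0.5, 0.5, 2)
      intervals[hit] <- intervals[hit] * factor
    }
  }
  rr_series(intervals)
}

default_index_params <- function() {
  # Means/SDs are simulation conveniences on the scale of each index for
  # older adults at rest (post-exercise shifts applied on top); they are
  # not population estimates.
  data.frame(
    index_name = c("mean_rr", "rmssd", "sdnn", "hf", "lf", "vlf",
                   "pns", "sns", "stress"),
    mean = c(850, 25, 35, 300, 400, 200, -0.5, 1.0, 12),
    exercise_effect = c(-150, -8, -10, -120, -150, -60, -1.0, 1.5, 3),
    between_sd = c(80, 10, 12, 150, 120, 80, 0.9, 1.2, 4),
    target_ccc = c(0.87, 0.72, 0.65, 0.45, 0.38, 0.34, 0.77, 0.84, 0.72),
    session_shift = rep(0, 9),
    stringsAsFactors = FALSE
  )
}

# Given a target CCC, the between-subject SD and the systematic session
# shift, solve for the within-subject (session) SD:
#   CCC = tau^2 / (tau^2 + sigma_w^2 + shift^2 / 2)
solve_within_sd <- function(between_sd, target_ccc, session_shift = 0) {
  if (target_ccc <= -1 || target_ccc >= 1 || target_ccc == 0)
    stop_hrv("solver", "target CCC must be in (-1, 1) and non-zero")
  w2 <- between_sd^2 * (1 - target_ccc) / target_ccc - session_shift^2 / 2
  if (!is.finite(w2) || w2 <= 0)
    stop_hrv("solver",
             "target CCC %.3f unattainable with between-SD %.3g and shift %.3g",
             target_ccc, between_sd, session_shift)
  sqrt(w2)
}

#' Configuration for a synthetic test-retest cohort
#'
#' Defaults mirror the study conditions the package is designed around:
#' 105 community-dwelling older adults (78.1% female, age 70.9 +/- 5.9
#' years), each measured in two sessions on the same day, before and
#' immediately after a 2-minute step test, yielding a 2 x 2 grid of
#' recordings per subject and nine HRV indices per recording. Per-index
#' values follow `subject effect + session shift + exercise effect + noise`
#' with the within-subject SD solved from the target between-session
#' concordance.
#'
#' @param n_subjects Number of subjects (default 105).
#' @param female_fraction Fraction of female subjects (default 0.781).
#' @param age_mean,age_sd Age distribution in years (default 70.9 / 5.9,
#'   truncated below at 60, the inclusion threshold).
#' @param index_params Data frame with columns `index_name`, `mean`,
#'   `exercise_effect`, `between_sd`, `target_ccc`, `session_shift`.
#' @param intensity_mean,intensity_sd Exercise intensity during the step
#'   test as a fraction of age-predicted maximum heart rate
#'   (default 0.67 +/- 0.10, truncated to \[0.3, 1\]).
#' @param seed Global integer seed; per-subject substreams are derived from
#'   it so that subject subsets are reproducible.
#' @return A `cohort_synth_config` list with the derived `within_sd` added
#'   to `index_params`.
#' @export
cohort_synth_config <- function(n_subjects = 105L, female_fraction = 0.781,
                                age_mean = 70.9, age_sd = 5.9,
                                index_params = default_index_params(),
                                intensity_mean = 0.67, intensity_sd = 0.10,
                                seed = 1L) {
  need <- c("index_name", "mean", "exercise_effect", "between_sd",
            "target_ccc", "session_shift")
  if (!all(need %in% names(index_params)))
    stop_hrv("configuration", "index_params must have columns: %s",
             paste(need, collapse = ", "))
  if (any(index_params$between_sd <= 0))
    stop_hrv("configuration", "between-subject SDs must be positive")
  if (age_sd <= 0)
    stop_hrv("configuration", "age_sd must be positive")
  index_params$within_sd <- mapply(
    solve_within_sd, index_params$between_sd, index_params$target_ccc,
    index_params$session_shift)
  structure(list(n_subjects = as.integer(n_subjects),
                 female_fraction = female_fraction,
                 age_mean = age_mean, age_sd = age_sd,
                 index_params = index_params,
                 intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd,
                 seed = as.integer(seed)),
            class = "cohort_synth_config")
}

subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 7919 * i) %% .Machine$integer.max)
}

#' Generate a synthetic test-retest cohort
#'
#' Draws one subject at a time from an independent seeded substream:
#' age and sex, a per-index subject random effect shared across the four
#' recordings, independent within-subject noise per session x condition,
#' and an exercise heart rate per session for the intensity summaries.
#' The generating parameters (ground truth) are embedded in the result for
#' parameter-recovery studies.
#'
#' @param config A [cohort_synth_config()].
#' @return A `cohort_dataset`: list with `subjects` (subject_id, age, sex),
#'   `grid` (one row per subject x session x condition, one column per
#'   index), `hr_exercise` (subject_id, session, hr_bpm) and `ground_truth`
#'   (the index parameter table and cohort settings).
#' @export
generate_cohort <- function(config = cohort_synth_config()) {
  stopifnot(inherits(config, "cohort_synth_config"))
  p <- config$index_params
  nidx <- nrow(p)
  subj_rows <- vector("list", config$n_subjects)
  grid_rows <- vector("list", config$n_subjects)
  hr_rows <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    set.seed(subject_seed(config$seed, i))
    id <- sprintf("S%03d", i)
    age <- max(60, stats::rnorm(1, config$age_mean, config$age_sd))
    sex <- if (stats::runif(1) < config$female_fraction) "F" else "M"
    b <- stats::rnorm(nidx, 0, p$between_sd)      # subject random effects
    cells <- expand.grid(session = 1:2, condition = c("pre", "post"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    vals <- matrix(NA_real_, nrow(cells), nidx,
                   dimnames = list(NULL, p$index_name))
    for (k in seq_len(nrow(cells))) {
      shift <- if (cells$session[k] == 2L) p$session_shift else 0
      eff <- if (cells$condition[k] == "post") p$exercise_effect else 0
      vals[k, ] <- p$mean + eff + b + shift + stats::rnorm(nidx, 0, p$within_sd)
    }
    inten <- pmin(1, pmax(0.3, stats::rnorm(
      2, config$intensity_mean, config$intensity_sd)))
    subj_rows[[i]] <- data.frame(subject_id = id, age = age, sex = sex,
                                 stringsAsFactors = FALSE)
    grid_rows[[i]] <- cbind(
      data.frame(subject_id = id, session = cells$session,
                 condition = cells$condition, stringsAsFactors = FALSE),
      as.data.frame(vals))
    hr_rows[[i]] <- data.frame(subject_id = id, session = 1:2,
                               hr_bpm = inten * (220 - age),
                               stringsAsFactors = FALSE)
  }
  structure(list(
    subjects = do.call(rbind, subj_rows),
    grid = do.call(rbind, grid_rows),
    hr_exercise = do.call(rbind, hr_rows),
    ground_truth = list(index_params = p,
                        n_subjects = config$n_subjects,
                        age_mean = config$age_mean, age_sd = config$age_sd,
                        female_fraction = config$female_fraction,
                        intensity_mean = config$intensity_mean,
                        seed = config$seed)
  ), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d subjects x 2 sessions x 2 conditions x %d indices\n",
              nrow(x$subjects), ncol(x$grid) - 3L))
  invisible(x)
}

#' Long-format view of a cohort's measurement grid
#'
#' One row per subject x session x condition x index, the shape consumed
#' by [run_study()]. Errors if any cell of the 2 x 2 recording grid is
#' missing, naming the offending cell.
#'
#' @param dataset A `cohort_dataset`, or its `grid` data frame.
#' @return A data frame with columns `subject_id`, `session`, `condition`,
#'   `index_name`, `value`.
#' @export
cohort_to_long <- function(dataset) {
  grid <- if (inherits(dataset, "cohort_dataset")) dataset$grid else dataset
  key_cols <- c("subject_id", "session", "condition")
  idx_cols <- setdiff(names(grid), key_cols)
  # completeness of the 2 x 2 grid per subject
  for (id in unique(grid$subject_id)) {
    g <- grid[grid$subject_id == id, ]
    for (s in 1:2) for (cond in c("pre", "post")) {
      if (!any(g$session == s & g$condition == cond))
        stop_hrv("missing_cell",
                 "subject %s is missing the session %d / %s recording",
                 id, s, cond)
    }
  }
  long <- do.call(rbind, lapply(idx_cols, function(nm) {
    data.frame(subject_id = grid$subject_id, session = grid$session,
               condition = grid$condition, index_name = nm,
               value = grid[[nm]], stringsAsFactors = FALSE)
  }))
  long[order(long$subject_id, long$session, long$condition, long$index_name), ,
       drop = FALSE] -> long
  rownames(long) <- NULL
  long
}

#' Pivot a long measurement table back to the grid shape
#'
#' Inverse of [cohort_to_long()]; the round trip is lossless.
#'
#' @param long A long data frame with columns `subject_id`, `session`,
#'   `condition`, `index_name`, `value`.
#' @return A grid data frame (one column per index).
#' @export
long_to_grid <- function(long) {
  idx <- sort(unique(long$index_name))
  keys <- unique(long[c("subject_id", "session", "condition")])
  keys <- keys[order(keys$subject_id, keys$session, keys$condition), ,
               drop = FALSE]
  rownames(keys) <- NULL
  for (nm in idx) {
    sub <- long[long$index_name == nm, ]
    m <- merge(keys, sub[c("subject_id", "session", "condition", "value")],
               by = c("subject_id", "session", "condition"), all.x = TRUE,
               sort = FALSE)
    m <- m[order(m$subject_id, m$session, m$condition), , drop = FALSE]
    keys[[nm]] <- m$value
  }
  keys
}

#' Write a cohort dataset to disk
#'
#' Emits the subject manifest, the long measurement table, the exercise
#' heart rates and a ground-truth JSON sidecar into `dir`.
#'
#' @param dataset A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort_to_long(dataset), file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$hr_exercise, file.path(dir, "hr_exercise.csv"),
                   row.names = FALSE)
  jsonlite::write_json(dataset$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
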