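#' Study configuration for the full reliability analysis
#'
#' Exactly one input source must be given: a long-format measurement table
#' (data frame or CSV path with columns `subject_id`, `session`,
#' `condition`, `index_name`, `value`), an existing `cohort_dataset`, or a
#' [cohort_synth_config()] describing a cohort to simulate.
#'
#' @param measurements Long measurement table or CSV path, or `NULL`.
#' @param cohort A `cohort_dataset` or [cohort_synth_config()], or `NULL`.
#' @param mcmc An [mcmc_config()] used for every difference model.
#' @param rope_multiplier ROPE half-width as a fraction of the response SD
#'   (default 0.1).
#' @param prior_multiplier Prior scale as a multiple of the response SD
#'   (default 2.5).
#' @param ccc_draws Posterior draws for each concordance model.
#' @param hrmax_formula Age-predicted maximum heart rate formula for the
#'   intensity summaries ([pct_hrmax()]).
#' @param bf_method Posterior-density estimator for the Savage-Dickey
#'   Bayes factor.
#' @param seed Integer master seed; per-model seeds are derived from it.
#' @param verbose Emit per-stage progress messages.
#' @return A `study_config` list.
#' @export
study_config <- function(measurements = NULL, cohort = NULL,
                         mcmc = mcmc_config(), rope_multiplier = 0.1,
                         prior_multiplier = 2.5, ccc_draws = 4000L,
                         hrmax_formula = "fox", bf_method = "analytic",
                         seed = 1L, verbose = FALSE) {
  if (is.null(measurements) == is.null(cohort))
    stop_hrv("configuration",
             "exactly one input source (measurements xor cohort) is required")
  structure(list(measurements = measurements, cohort = cohort,
                 mcmc = mcmc, rope_multiplier = rope_multiplier,
                 prior_multiplier = prior_multiplier,
                 ccc_draws = as.integer(ccc_draws),
                 hrmax_formula = hrmax_formula, bf_method = bf_method,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "study_config")
}

#' Run the full test-retest reliability analysis
#'
#' For every HRV index and each condition (pre- and post-exercise,
#' analysed as fully independent blocks): forms the per-subject
#' between-session differences (session 2 minus session 1), removes
#' extreme outliers with the 3 x IQR box-plot rule, builds the
#' zero-centred prior from the retained differences, fits the
#' intercept-only Bayesian model and summarises it in SEXIT style; in
#' parallel computes the Bayesian Lin's concordance coefficient and the
#' Bland-Altman limits of agreement on the raw session pairs (outlier
#' removal in the difference models does not propagate to the agreement
#' analysis). If the input carries exercise heart rates and ages, the
#' relative intensity (%HRmax) is summarised per session.
#'
#' A failed convergence gate flags the affected rows (`pass = FALSE`)
#' without aborting; structural errors abort with the stage and the
#' offending index named.
#'
#' @param config A [study_config()].
#' @return A `reliability_report`: list with data frames `delta_summary`
#'   (per index x condition SEXIT summary), `concordance`, `bland_altman`,
#'   `hrmax` (or `NULL`) and a `metadata` list (seed, settings, package
#'   version).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  say <- function(msg, ...) if (config$verbose) message(sprintf(msg, ...))

  dataset <- NULL
  if (!is.null(config$cohort)) {
    dataset <- if (inherits(config$cohort, "cohort_synth_config")) {
      say("simulating cohort (%d subjects)", config$cohort$n_subjects)
      generate_cohort(config$cohort)
    } else config$cohort
    long <- cohort_to_long(dataset)
  } else {
    long <- if (is.character(config$measurements))
      read_measurements_csv(config$measurements) else config$measurements
    need <- c("subject_id", "session", "condition", "index_name", "value")
    if (!all(need %in% names(long)))
      stop_hrv("configuration", "measurements must have columns: %s",
               paste(need, collapse = ", "))
  }
  indices <- sort(unique(long$index_name))
  conditions <- intersect(c("pre", "post"), unique(long$condition))
  say("analysing %d indices x %d conditions, %d measurement rows",
      length(indices), length(conditions), nrow(long))

  delta_rows <- list(); ccc_rows <- list(); ba_rows <- list()
  k <- 0L
  for (cond in conditions) {
    for (idx in indices) {
      k <- k + 1L
      sub <- long[long$condition == cond & long$index_name == idx, ]
      wide <- merge(sub[sub$session == 1L, c("subject_id", "value")],
                    sub[sub$session == 2L, c("subject_id", "value")],
                    by = "subject_id", suffixes = c("_s1", "_s2"))
      wide <- wide[stats::complete.cases(wide), ]
      res <- tryCatch({
        x <- wide$value_s1
        y <- wide$value_s2
        delta <- y - x
        filt <- remove_extreme_outliers(delta)
        prior <- build_prior(filt$values, config$prior_multiplier)
        # seed derived from the model identity, not the loop order, so a
        # change to one index never perturbs another index's draws
        tag <- sum(utf8ToInt(paste(idx, cond, sep = "|")) *
                     seq_along(utf8ToInt(paste(idx, cond, sep = "|"))))
        fit_seed <- as.integer((as.numeric(config$seed) * 131 + tag * 17) %%
                                 .Machine$integer.max)
        fit <- fit_intercept_model(
          filt$values, prior,
          mcmc_config(config$mcmc$chains, config$mcmc$iterations,
                      config$mcmc$warmup, seed = fit_seed))
        sx <- sexit_summary(fit, response_sd = stats::sd(filt$values),
                            rope_multiplier = config$rope_multiplier,
                            bf_method = config$bf_method)
        ccc <- bayesian_ccc(x, y, n_draws = config$ccc_draws,
                            seed = fit_seed + 1L)
        ba <- bland_altman(x, y)
        list(sx = sx, ccc = ccc, ba = ba,
             n = length(delta), n_removed = length(filt$removed))
      }, hrv_error = function(e) {
        stop_hrv("stage_failure", "index %s (%s): %s", idx, cond,
                 conditionMessage(e))
      })
      say("  %s / %s: n = %d (%d outliers removed), BF10 = %.3f",
          idx, cond, res$n, res$n_removed, res$sx$bf10)
      delta_rows[[k]] <- data.frame(
        index_name = idx, condition = cond, n = res$n,
        n_outliers_removed = res$n_removed,
        median = res$sx$median, ci_low = res$sx$hdi_low,
        ci_high = res$sx$hdi_high, pd = res$sx$pd,
        rope_low = res$sx$rope_low, rope_high = res$sx$rope_high,
        rope_pct_inside = res$sx$rope_pct_inside,
        rope_label = res$sx$rope_label,
        rhat = res$sx$rhat, ess = res$sx$ess,
        bf10 = res$sx$bf10, bf_label = res$sx$bf_label,
        pass = res$sx$pass, stringsAsFactors = FALSE)
      ccc_rows[[k]] <- data.frame(
        index_name = idx, condition = cond, ccc = res$ccc$ccc_median,
        interpretation = res$ccc$label, ci_low = res$ccc$ci_low,
        ci_high = res$ccc$ci_high, stringsAsFactors = FALSE)
      ba_rows[[k]] <- data.frame(
        index_name = idx, condition = cond, bias = res$ba$bias,
        loa_low = res$ba$loa_low, loa_high = res$ba$loa_high,
        stringsAsFactors = FALSE)
    }
  }

  hrmax <- NULL
  if (!is.null(dataset) && !is.null(dataset$hr_exercise))
    hrmax <- summarize_hrmax(dataset, formula = config$hrmax_formula)

  structure(list(
    delta_summary = do.call(rbind, delta_rows),
    concordance = do.call(rbind, ccc_rows),
    bland_altman = do.call(rbind, ba_rows),
    hrmax = hrmax,
    metadata = list(
      seed = config$seed,
      chains = config$mcmc$chains, iterations = config$mcmc$iterations,
      warmup = config$mcmc$warmup,
      rope_multiplier = config$rope_multiplier,
      prior_multiplier = config$prior_multiplier,
      ccc_draws = config$ccc_draws, bf_method = config$bf_method,
      hrmax_formula = config$hrmax_formula,
      package_version = as.character(utils::packageVersion("hrvretest")))
  ), class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %d difference models, %d concordance models\n",
              nrow(x$delta_summary), nrow(x$concordance)))
  invisible(x)
}

#' Relative exercise intensity per session
#'
#' Median and central 95% empirical interval of per-subject %HRmax
#' (exercise heart rate over the age-predicted maximum) for each session.
#'
#' @param dataset A `cohort_dataset` with `hr_exercise` and subject ages,
#'   or a list with `subjects` and `hr_exercise` data frames.
#' @param formula Passed to [pct_hrmax()].
#' @return Data frame with `session`, `n`, `median`, `q2.5`, `q97.5`
#'   (percent of age-predicted maximum heart rate).
#' @export
summarize_hrmax <- function(dataset, formula = "fox") {
  hr <- dataset$hr_exercise
  subj <- dataset$subjects
  if (is.null(hr) || nrow(hr) == 0)
    stop_hrv("invalid_input", "no exercise heart-rate records present")
  m <- merge(hr, subj[c("subject_id", "age")], by = "subject_id")
  if (anyNA(m$age)) {
    bad <- m$subject_id[is.na(m$age)][1]
    stop_hrv("invalid_input", "subject %s has no recorded age", bad)
  }
  out <- lapply(sort(unique(m$session)), function(s) {
    g <- m[m$session == s, ]
    if (nrow(g) == 0) stop_hrv("invalid_input", "session %s is empty", s)
    pct <- pct_hrmax(g$hr_bpm, g$age, formula)
    data.frame(session = s, n = nrow(g),
               median = stats::median(pct),
               q2.5 = stats::quantile(pct, 0.025, names = FALSE),
               q97.5 = stats::quantile(pct, 0.975, names = FALSE))
  })
  do.call(rbind, out)
}

#' Write a reliability report to disk
#'
#' Emits the difference-model summary, concordance and Bland-Altman tables
#' as CSV, and the full report (tables plus metadata, full precision) as
#' JSON. Identical configuration and seed reproduce identical files.
#'
#' @param report A `reliability_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "reliability_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(round_report_table(report$delta_summary),
                   file.path(dir, "delta_summary.csv"), row.names = FALSE)
  utils::write.csv(report$concordance, file.path(dir, "concordance.csv"),
                   row.names = FALSE)
  utils::write.csv(report$bland_altman, file.path(dir, "bland_altman.csv"),
                   row.names = FALSE)
  if (!is.null(report$hrmax))
    utils::write.csv(report$hrmax, file.path(dir, "hrmax.csv"),
                     row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

# Display rounding for the CSV table: medians and interval bounds to 2
# decimals, pd to 0.1%, BF to 3 decimals. The JSON keeps full precision.
round_report_table <- function(df) {
  df$median <- round(df$median, 2)
  df$ci_low <- round(df$ci_low, 3)
  df$ci_high <- round(df$ci_high, 3)
  df$pd <- round(df$pd, 3)
  df$rope_pct_inside <- round(df$rope_pct_inside, 1)
  df$bf10 <- round(df$bf10, 3)
  df
}

#' Validate a report against the shipped schema
#'
#' Checks the structural contract of a `reliability_report` (or a report
#' read back from `report.json`) against the JSON schema shipped in
#' `inst/extdata/report-schema.json`: required blocks, required columns
#' and value ranges.
#'
#' @param report A `reliability_report` or a list parsed from the JSON.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(
    system.file("extdata", "report-schema.json", package = "hrvretest"))
  for (block in unlist(schema$required)) {
    if (is.null(report[[block]]))
      stop_hrv("schema", "report is missing the '%s' block", block)
  }
  col_req <- function(block, cols) {
    have <- names(report[[block]])
    miss <- setdiff(cols, have)
    if (length(miss))
      stop_hrv("schema", "report$%s is missing column(s): %s", block,
               paste(miss, collapse = ", "))
  }
  col_req("delta_summary",
          unlist(schema$properties$delta_summary$required_columns))
  col_req("concordance",
          unlist(schema$properties$concordance$required_columns))
  col_req("bland_altman",
          unlist(schema$properties$bland_altman$required_columns))
  ds <- as.data.frame(report$delta_summary)
  if (any(ds$pd < 0.5 | ds$pd > 1))
    stop_hrv("schema", "pd values must lie in [0.5, 1]")
  if (any(ds$rope_pct_inside < 0 | ds$rope_pct_inside > 100))
    stop_hrv("schema", "ROPE percentages must lie in [0, 100]")
  cc <- as.data.frame(report$concordance)
  if (any(cc$ccc < -1 | cc$ccc > 1))
    stop_hrv("schema", "CCC values must lie in [-1, 1]")
  invisible(TRUE)
}
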