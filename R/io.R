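#' Read a Polar-style R-R interval export
#'
#' Reads a plain-text file with one beat-to-beat interval (in milliseconds)
#' per line, the dialect produced by Polar chest-strap exports. Blank lines
#' and lines starting with `#` are skipped.
#'
#' @param path Path to the text file.
#' @inheritParams rr_series
#' @return An [rr_series()].
#' @export
read_rr_file <- function(path, subject_id = NA_character_,
                         condition = "pre", session = 1L) {
  if (!file.exists(path))
    stop_hrv("invalid_input", "RR file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals))
    stop_hrv("invalid_input", "non-numeric line(s) in RR file %s", path)
  rr_series(vals, subject_id = subject_id, condition = condition,
            session = session)
}

#' Write an R-R series in the plain-text dialect
#'
#' One interval in milliseconds per line, readable by [read_rr_file()].
#'
#' @param series An [rr_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rr_file <- function(series, path) {
  stopifnot(is_rr_series(series))
  writeLines(format(series$intervals, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Read a multi-recording R-R interval CSV
#'
#' Reads a long CSV with columns `subject_id`, `session`, `condition`,
#' `rr_ms` (one beat per row, in recording order within each group) and
#' splits it into one [rr_series()] per recording.
#'
#' @param path Path to the CSV file.
#' @return A list of [rr_series()], one per (subject, session, condition).
#' @export
read_rr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session", "condition", "rr_ms")
  if (!all(need %in% names(df)))
    stop_hrv("invalid_input", "RR CSV must have columns: %s",
             paste(need, collapse = ", "))
  keys <- interaction(df$subject_id, df$session, df$condition, drop = TRUE)
  lapply(split(df, keys), function(g) {
    rr_series(g$rr_ms, subject_id = g$subject_id[1],
              condition = g$condition[1], session = as.integer(g$session[1]))
  })
}

#' Read a long-format HRV measurement table
#'
#' Reads precomputed HRV measurements in long format with columns
#' `subject_id`, `session`, `condition`, `index_name`, `value` — the shape
#' consumed by [run_study()].
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with the five columns above.
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session", "condition", "index_name", "value")
  if (!all(need %in% names(df)))
    stop_hrv("invalid_input", "measurement CSV must have columns: %s",
             paste(need, collapse = ", "))
  df$session <- as.integer(df$session)
  df
}

#' Flatten HRV features of one recording to a one-row data frame
#'
#' @param features An `hrv_features` object from [compute_all()].
#' @return A one-row `data.frame` keyed by subject/session/condition.
#' @export
features_as_row <- function(features) {
  stopifnot(inherits(features, "hrv_features"))
  meta <- attr(features, "recording")
  vals <- unclass(features)
  cbind(
    data.frame(subject_id = meta$subject_id, session = meta$session,
               condition = meta$condition, stringsAsFactors = FALSE),
    as.data.frame(vals[!vapply(vals, is.null, logical(1))])
  )
}

#' Write per-recording feature rows to CSV
#'
#' @param feature_list A list of `hrv_features` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(feature_list, path) {
  rows <- do.call(rbind, lapply(feature_list, features_as_row))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
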