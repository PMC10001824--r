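#' Remove extreme outliers with 3 x IQR box-plot fences
#'
#' Single-pass removal of values strictly above `Q3 + 3 * IQR` or strictly
#' below `Q1 - 3 * IQR`, the conventional "extreme outlier" box-plot rule.
#' Quartiles use linear interpolation (R's default type-7 convention).
#' Values exactly on a fence are retained. Fences are computed once from the
#' full sample; removal is never iterated.
#'
#' @param values Numeric vector, length at least 4.
#' @return A list with `values` (retained), `removed` (indices into the
#'   input) and `fences` (`c(lower, upper)`).
#' @examples
#' remove_extreme_outliers(c(1:9, 1000))$removed
#' @export
remove_extreme_outliers <- function(values) {
  if (length(values) < 4L)
    stop_hrv("invalid_input", "outlier fences need at least 4 values, got %d",
             length(values))
  if (anyNA(values) || any(!is.finite(values)))
    stop_hrv("invalid_input", "values must be finite and non-missing")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - 3 * iqr, q[2] + 3 * iqr)
  removed <- which(values < fences[1] | values > fences[2])
  # with fences from the full sample the quartiles themselves always remain
  stopifnot(length(removed) < length(values))
  list(
    values = if (length(removed)) values[-removed] else values,
    removed = removed,
    fences = fences
  )
}
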