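# Classed conditions so callers and tests can distinguish failure modes
# without matching message text.

stop_hrv <- function(class, msg, ..., data = NULL) {
  cnd <- structure(
    class = c(paste0("hrv_", class), "hrv_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1), data = data)
  )
  stop(cnd)
}

warn_hrv <- function(class, msg, ...) {
  cnd <- structure(
    class = c(paste0("hrv_", class), "hrv_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  )
  warning(cnd)
}
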