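# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# reverse cumulative sum: out[i] = sum(x[i:length(x)])
revcumsum <- function(x) rev(cumsum(rev(x)))

# classed conditions so callers can distinguish config, data and estimation
# failures programmatically
stop_canlife <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "canlife_error", "error", "condition")))
}

stop_config <- function(msg) stop_canlife(msg, "canlife_config_error")
stop_data <- function(msg) stop_canlife(msg, "canlife_data_error")
stop_estimation <- function(msg) stop_canlife(msg, "canlife_estimation_error")

# strict ISO-8601 (or explicit format) date parsing; invalid strings map to NA
parse_date_strict <- function(x, format = "%Y-%m-%d") {
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_character_, length(x)))
  present <- !is.na(x) & nzchar(x)
  parsed <- as.Date(x[present], format = format)
  # as.Date() tolerates e.g. "2016-2-3"; round-trip to reject zero-padded
  # mismatches only when the canonical format is in use
  if (format == "%Y-%m-%d") {
    bad <- !is.na(parsed) & format(parsed, format) != x[present]
    parsed[bad] <- as.Date(NA)
  }
  out[present] <- parsed
  out
}

# full-precision numeric rendering that round-trips doubles exactly
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}
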