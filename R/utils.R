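# Internal helpers shared across modules.

# Half-up rounding: report tables round 84.25 -> 84.3, not to even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Days per model cycle and per year; a model "year" is four 90-day cycles,
# calendar conversion uses the 365.25-day average year.
CYCLE_DAYS <- 90
YEAR_DAYS <- 365.25
CYCLE_YEARS <- CYCLE_DAYS / YEAR_DAYS

stop_config <- function(msg, field = NULL) {
  abort(msg, class = "scadcost_config_error", field = field)
}

stop_data <- function(msg, ...) {
  abort(msg, class = "scadcost_data_error", ...)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop_config(sprintf("`%s` must be a probability in [0, 1]", name), field = name)
  }
  invisible(x)
}

# Atomic write: stage in a temp file in the same directory, then rename,
# so a crashed run never leaves a half-written output.
write_atomic <- function(write_fn, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp.", basename(path)))
  write_fn(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  write_atomic(function(tmp) readr::write_csv(df, tmp), path)
}

write_json_atomic <- function(x, path) {
  write_atomic(
    function(tmp) jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    path
  )
}
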