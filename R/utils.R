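# Internal helpers: rounding and argument validation.

# Round half away from zero (the convention used for report output), unlike
# base round()'s round-half-even. A tiny epsilon guards against binary
# representation error at exact .5 boundaries.
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Check a numeric vector lies in an interval; bounds may be open or closed.
assert_in_range <- function(x, name, lower = 0, upper = 1,
                            lower_open = FALSE, upper_open = FALSE,
                            allow_na = FALSE) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric.", name))
  }
  bad_na <- is.na(x)
  if (any(bad_na) && !allow_na) {
    abort(sprintf("`%s` contains missing values.", name))
  }
  v <- x[!is.na(x)]
  lo_ok <- if (lower_open) v > lower else v >= lower
  hi_ok <- if (upper_open) v < upper else v <= upper
  if (!all(lo_ok & hi_ok)) {
    abort(sprintf(
      "`%s` must lie in %s%g, %g%s.", name,
      if (lower_open) "(" else "[", lower, upper,
      if (upper_open) ")" else "]"
    ))
  }
  invisible(x)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  invisible(x)
}
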