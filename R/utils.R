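## Classed conditions so callers (and tests) can distinguish failure modes.
qts_error <- function(subclass, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(subclass, "qtsalvage_error"),
                      call = call))
}

qts_check <- function(ok, subclass, msg) {
  if (!isTRUE(ok)) qts_error(subclass, msg, call = sys.call(-1))
  invisible(TRUE)
}

## Scalar validators --------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  qts_check(is.numeric(x) && length(x) == 1L && is.finite(x),
            "invalid_parameter",
            sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  qts_check(lo_ok && x <= upper, "invalid_parameter",
            sprintf("`%s` = %g outside allowed range", name, x))
  invisible(x)
}

check_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  check_number(seed, "seed")
  invisible(as.integer(seed))
}

## Half-sine arch with compact support: zero outside [onset, onset + dur],
## amplitude `amp` at the midpoint, nonzero slope at both ends.  Evaluated on
## a time grid `t` (seconds).
half_sine <- function(t, onset, dur, amp) {
  x <- (t - onset) / dur
  v <- numeric(length(t))
  inside <- x > 0 & x < 1
  v[inside] <- amp * sin(pi * x[inside])
  v
}

## %LV helper
pct_of <- function(part, whole) 100 * part / whole
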