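# shared validation helpers; all user-facing errors carry an hrvci_error_*
# class so callers (and the test suite) can match them by name.

stop_hrvci <- function(class, message, ...) {
  rlang::abort(message, class = c(class, "hrvci_error"), ...)
}

warn_hrvci <- function(class, message, ...) {
  rlang::warn(message, class = c(class, "hrvci_warning"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_hrvci("hrvci_error_bad_argument",
               sprintf("`%s` must be a single finite number in [%s, %s].",
                       name, format(lower), format(upper)))
  }
  invisible(x)
}

# round-half-up next composite length with small prime factors, for fast FFTs
composite_length <- function(n) {
  stats::nextn(n, factors = c(2L, 3L, 5L))
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# seed handling: evaluate `expr` under a local RNG stream when `seed` is given,
# leaving the caller's RNG state untouched; otherwise use the global stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
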