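# Internal helpers: argument checking and seed handling.

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "polystate_validation_error")
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    abort(sprintf("`%s` = %s is outside the allowed range.", name, format(x)),
          class = "polystate_validation_error")
  }
  invisible(x)
}

assert_count <- function(x, name, minimum = 0L) {
  assert_scalar_number(x, name, lower = minimum)
  if (x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer.", name),
          class = "polystate_validation_error")
  }
  invisible(as.integer(x))
}

assert_seed <- function(seed) {
  if (is.null(seed)) {
    abort("A `seed` is required for reproducible simulation or permutation.",
          class = "polystate_validation_error")
  }
  assert_count(seed, "seed")
}

# Deterministic sub-seed derived from a master seed and a stream index, so
# independent stages/pairs get independent, order-invariant RNG streams.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483647)
}

with_seed_ <- function(seed, code) {
  withr::with_seed(seed, code)
}
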