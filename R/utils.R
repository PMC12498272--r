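# Internal helpers shared across modules.

# Derive a per-iteration RNG seed from a base seed and a counter.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) %% 2147483647 * 48271 + i * 7919) %% 2147483647)
}

# Round-half-up to the nearest integer: bin k covers [k - 0.5, k + 0.5).
# base::round() rounds half to even, which is the wrong convention here.
round_half_up <- function(x) floor(x + 0.5)

stop_bad_arg <- function(..., call. = FALSE) stop(..., call. = call.)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_bad_arg(sprintf("'%s' must be a single finite number in [%s, %s]",
                         name, format(lower), format(upper)))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
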