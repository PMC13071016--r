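# Internal helpers shared across modules.

# Deterministic 32-bit sub-seed derived from a base seed and integer keys,
# so independent random streams (per client, per round, per pair) never
# collide and every public operation is a pure function of (inputs, seed).
derive_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  h <- 0
  for (k in keys) h <- (h * 69069 + (as.numeric(k) %% 2147483647)) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister")
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
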