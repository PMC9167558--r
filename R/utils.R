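# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream; a NULL seed leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Derive a reproducible sub-stream seed from a master seed; stays inside the
# 32-bit integer range so it is always a valid `set.seed()` argument.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  s <- (as.double(seed) %% 2147483647) * 48271 + 7919 * as.double(k)
  as.integer(s %% 2147483647)
}

is_wholenumber <- function(x, tol = 1e-8) {
  abs(x - round(x)) < tol
}
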