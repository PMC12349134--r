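# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a sprintf-style message, without the call in the condition.
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_proportion <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (x > 0 || (allow_zero && x == 0)) && (x < 1 || (allow_one && x == 1))
  if (!ok) fail("`%s` must be a proportion in [0, 1]; got %s", name, format(x))
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
  if (!ok) fail("`%s` must be an integer >= %d; got %s", name, min, format(x))
  invisible(as.integer(x))
}

# Derive a stream-specific 32-bit seed from a base seed, so independent
# random decisions (weights, shuffling, folds, ...) never share a stream.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12347L) %% 2147483629L
}

# Column means / sds ignoring NA, never dropping to vectors.
col_means <- function(x) colMeans(x, na.rm = TRUE)
col_sds <- function(x) {
  n <- colSums(!is.na(x))
  m <- colMeans(x, na.rm = TRUE)
  sq <- colMeans(x^2, na.rm = TRUE)
  sqrt(pmax(0, (sq - m^2) * n / pmax(1, n - 1)))
}
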