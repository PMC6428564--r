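# Internal helpers: seeded evaluation and argument checks.

# Evaluate `code` under a fixed RNG seed when `seed` is non-NULL, restoring
# the caller's RNG state afterwards; with seed = NULL the global stream is
# used as-is.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Deterministic child seed for a named stream, kept below 2^31.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  offset <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) + offset * 1009L) %% 2147483587L
}

stopifnot_scalar_number <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
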