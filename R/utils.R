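# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. If seed is NULL the current stream is used as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_numeric_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x)) stopf("`%s` must be numeric", name)
  if (length(x) < min_len) {
    stopf("`%s` must have length >= %d (got %d)", name, min_len, length(x))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stopf("`%s` contains NA or non-finite values", name)
  }
  invisible(x)
}
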