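`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("'%s' must be a single positive finite number", name)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stopf("'%s' must be a single non-negative finite number", name)
  invisible(x)
}

## Draw per-unit RNG sub-seeds from a top-level seed so each unit's stream is
## reproducible independently of how much randomness other units consume.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}
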