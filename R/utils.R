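#' @keywords internal
"_PACKAGE"

## NULL coalescing used throughout config handling
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive_int <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 1 || x != floor(x))
    stop_invalid("'%s' must be a positive integer (got %s)", name,
                 paste(format(x), collapse = ","))
  as.integer(x)
}

check_nonneg_int <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x != floor(x))
    stop_invalid("'%s' must be a non-negative integer", name)
  as.integer(x)
}

check_positive_real <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0)
    stop_invalid("'%s' must be a positive real number", name)
  as.numeric(x)
}

## Derive a per-stage seed from a global one, staying inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}
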