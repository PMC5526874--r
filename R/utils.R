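# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stopf(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1

# Seeds are mandatory for every randomized stage: silence here would make
# reruns irreproducible without anyone noticing.
require_seed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed))
    stopf("a seed is required for this randomized operation; none was supplied")
  assert_that(is_count(seed), "seed must be a single non-negative integer")
  as.integer(seed)
}

# Deterministic per-stage stream derived from a master seed; kept < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1000003 + offset) %% 2147483647)
}

log_msg <- function(fmt, ...) {
  message(sprintf("[cresig] %s", sprintf(fmt, ...)))
}
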