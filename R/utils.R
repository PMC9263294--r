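# Internal helpers shared across modules.

#' Round half-up to a fixed number of decimals
#'
#' Base `round()` rounds half-to-even; printed clinical tables round half-up.
#' @noRd
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Derive a child seed from a base seed and a stream index
#'
#' Keeps every derived seed a valid 32-bit integer so that independent
#' stages (cohort generation, splitting, each training replicate) get
#' reproducible, non-overlapping streams from one user-facing seed.
#' @noRd
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 69069 + 12345 * as.double(stream)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stopf("%s must lie in [0, 1]", what)
  }
  invisible(x)
}
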