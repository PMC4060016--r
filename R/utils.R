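# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Ordinary "half-up" rounding (8.74 -> 9, 0.275 -> 0.28), as opposed to
#' [base::round()]'s round-half-to-even. All reported densities and
#' occupancies use this convention; a tiny epsilon absorbs binary
#' representation error in decimal inputs (e.g. 100 * 39 / 114).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# floor() with a small guard so that products of printed decimals
# (0.27, 0.23, ...) that land on an integer are not pushed below it by
# binary representation error (13050 * 0.27 * 34 must floor to 119799).
floor_guard <- function(x) floor(x + 1e-9)

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. All generators route randomness through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream-specific child seed so stages consuming one user seed
# do not reuse the identical stream. Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  (as.double(seed) * 1103515245 + 12345 + 97 * stream) %% 2147483647
}

# Stage logging: plain messages, suppressible via option.
log_info <- function(...) {
  if (isTRUE(getOption("stepimpact.quiet", FALSE))) return(invisible(NULL))
  message("[stepimpact] ", sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
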