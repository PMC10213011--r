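# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero for nonnegative values
#'
#' Deterministic rounding used everywhere an intensity or a pixel dimension is
#' quantized, so outputs are bit-reproducible (base `round()` rounds half to
#' even). For the nonnegative quantities handled here this is round-half-up.
#'
#' @param x numeric vector or array, assumed >= -0.5.
#' @return `x` rounded to integers (storage mode unchanged).
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

# Population variance / standard deviation (divisor n, not n - 1).
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

# Structured error with a package condition class, so callers can
# discriminate parse/schema/scale failures programmatically.
br_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "benthicready_error")))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}
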