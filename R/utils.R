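# Shared small helpers.

#' Round half away from zero
#'
#' Percentage display rounding used throughout the package: nearest integer,
#' ties away from zero (so 38.5 -> 39, -0.5 -> -1). Base `round()` rounds half
#' to even, which does not match how results of this kind are conventionally
#' reported.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @export
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_stage <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

warn_stage <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}
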