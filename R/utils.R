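#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals, matching how the
#' reference tables print their values (R's `round()` rounds half to
#' even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric of the same shape.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}
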