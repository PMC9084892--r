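#' Gas constant in kcal mol^-1 K^-1
#'
#' All free energies in this package are in kcal/mol, so the gas constant
#' is carried in the same units.
#'
#' @format A length-one numeric, 1.9872e-3 kcal mol^-1 K^-1.
#' @export
R_GAS <- 1.9872e-3

#' Convert degrees Celsius to kelvin
#'
#' Temperatures are stored in kelvin internally; degrees Celsius are
#' accepted only at user-facing boundaries.
#'
#' @param temp_c Temperature in degrees Celsius.
#' @return Temperature in kelvin.
#' @export
celsius_to_kelvin <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  temp_c + 273.15
}

## internal validation helper: scalar finite numeric
.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
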