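#' Insulin unit-to-molar conversion factor
#'
#' Bridge between clinical insulin units and molar concentration:
#' 1 U/ml corresponds to 6.94e6 pmol/L (equivalently 1 uU/ml = 6.94 pM).
#' This is the convention under which the published aggregation coefficients
#' for the Semilente, Actrapid and Lispro formulations are mutually
#' consistent to their printed two significant figures.
#'
#' @return Scalar conversion factor in (pmol/L) per (U/ml).
#' @export
#' @examples
#' insulin_unit_factor()
insulin_unit_factor <- function() 6.94e6

#' Convert a dimer-to-hexamer aggregation coefficient to SI-style units
#'
#' Aggregation coefficients for insulin formulations are tabulated in
#' ml^2/U^2 in the subcutaneous-absorption literature. The kinetic model
#' works in picomolar concentrations, so the coefficient must be expressed
#' in L^2/pmol^2. Because the coefficient multiplies a squared
#' concentration, the conversion divides by the squared unit factor.
#'
#' @param value Aggregation coefficient in ml^2/U^2. Must be nonnegative.
#' @param factor Conversion factor in (pmol/L)/(U/ml); defaults to
#'   [insulin_unit_factor()].
#' @return Coefficient in L^2/pmol^2.
#' @seealso [aggregation_coeff_from_si()] for the inverse.
#' @export
#' @examples
#' aggregation_coeff_to_si(7.6e-2) # Semilente, ~1.6e-15 L^2/pmol^2
aggregation_coeff_to_si <- function(value, factor = insulin_unit_factor()) {
  stopifnot(is.numeric(value), is.numeric(factor), factor > 0)
  if (any(value < 0)) {
    stop("aggregation coefficient must be nonnegative", call. = FALSE)
  }
  value / factor^2
}

#' @rdname aggregation_coeff_to_si
#' @param value_si Coefficient in L^2/pmol^2. Must be nonnegative.
#' @export
aggregation_coeff_from_si <- function(value_si, factor = insulin_unit_factor()) {
  stopifnot(is.numeric(value_si), is.numeric(factor), factor > 0)
  if (any(value_si < 0)) {
    stop("aggregation coefficient must be nonnegative", call. = FALSE)
  }
  value_si * factor^2
}

#' First-order rate constant from a half-life
#'
#' For exponential decay \eqn{I(t) = I_0 e^{-dt}}, the rate constant that
#' halves the amount in `t_half` minutes is \eqn{\ln 2 / t_{1/2}}. Used to
#' turn the circulating insulin half-life (4-6 min in vivo) into the
#' degradation rate of the kinetic model.
#'
#' @param t_half Half-life in minutes; must be strictly positive.
#' @return Rate constant in 1/min.
#' @export
#' @examples
#' rate_from_half_life(6)
rate_from_half_life <- function(t_half) {
  stopifnot(is.numeric(t_half))
  if (any(t_half <= 0)) {
    stop("half-life must be strictly positive", call. = FALSE)
  }
  log(2) / t_half
}
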