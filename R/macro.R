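#' Net influx rate constant
#'
#' The macro-parameter of irreversible FDG trapping,
#' \deqn{K_i = K_1 k_3 / (k_2 + k_3)} (ml/ml/min). Defined as 0 when
#' k2 + k3 = 0. Always satisfies Ki <= K1, and Ki = 0 when k3 = 0.
#'
#' @param params [fdg_params()] output (vectorized over rows) or a data frame
#'   with columns `K1`, `k2`, `k3`.
#' @return Numeric vector of Ki values.
#' @export
#' @examples
#' influx_constant(fdg_params(0.091, 0.128, 0.057))
influx_constant <- function(params) {
  K1 <- params$K1; k2 <- params$k2; k3 <- params$k3
  den <- k2 + k3
  ifelse(den > 0, K1 * k3 / den, 0)
}

#' Lumped constant from rate constants
#'
#' The FDG-to-glucose lumped constant under the conversion K1g = K1/tau,
#' k2g = k2/tau, k3g = k3/phi:
#' \deqn{LC = \frac{\phi k_2 + \tau k_3}{k_2 + k_3}}
#' the ratio of FDG to glucose net uptake. LC always lies between
#' min(phi, tau) and max(phi, tau), tends to phi as k3 -> 0, and increases
#' with k3 whenever tau > phi (so high-phosphorylation tissue carries the
#' highest LC).
#'
#' @param params [fdg_params()] output or data frame with `k2`, `k3`.
#' @param conv An [lc_conversion()] object.
#' @return Numeric vector of lumped constants; `NA` where k2 + k3 = 0
#'   (undefined), with a warning.
#' @export
#' @examples
#' lumped_constant(fdg_params(0.091, 0.128, 0.057), lc_conversion())
lumped_constant <- function(params, conv = lc_conversion()) {
  k2 <- params$k2; k3 <- params$k3
  den <- k2 + k3
  bad <- !is.na(den) & den <= 0
  if (any(bad)) warn("k2 + k3 = 0: lumped constant undefined, returning NA.")
  out <- (conv$phi * k2 + conv$tau * k3) / den
  out[bad] <- NA_real_
  out
}

#' Glucose metabolic rate from the influx constant
#'
#' \deqn{CMRG = 100 \cdot G_p \cdot K_i / LC} in micromol per 100 ml tissue
#' per min, with plasma glucose `G_p` in mmol/l (numerically micromol/ml).
#'
#' @param Ki Influx constant, ml/ml/min.
#' @param plasma_glucose Plasma glucose, mmol/l.
#' @param LC Lumped constant, must be positive.
#' @return CMRG in micromol/100 ml/min.
#' @export
#' @examples
#' cmrg_from_ki(0.030, 5.0, 0.50)
cmrg_from_ki <- function(Ki, plasma_glucose, LC) {
  if (any(LC <= 0, na.rm = TRUE)) abort("`LC` must be positive.")
  100 * plasma_glucose * Ki / LC
}

#' Steady-state brain tissue glucose concentration
#'
#' Free tissue glucose implied by the converted glucose rate constants,
#' \deqn{G_t = G_p \frac{K_1}{k_2 + (\tau/\phi) k_3}} in mmol/l: transport in
#' balances efflux plus phosphorylation at steady state. Raising k3 at fixed
#' K1, k2 strictly lowers G_t.
#'
#' @inheritParams lumped_constant
#' @param plasma_glucose Plasma glucose, mmol/l.
#' @return Numeric vector, mmol/l; `NA` (flagged by warning) where the
#'   denominator is zero.
#' @export
#' @examples
#' brain_glucose(fdg_params(0.091, 0.128, 0.057), 4.6, lc_conversion())
brain_glucose <- function(params, plasma_glucose, conv = lc_conversion()) {
  den <- params$k2 + (conv$tau / conv$phi) * params$k3
  bad <- !is.na(den) & den <= 0 & !is.na(params$K1) & params$K1 > 0
  if (any(bad)) warn("Degenerate denominator in brain glucose; returning NA.")
  out <- ifelse(params$K1 == 0, 0, plasma_glucose * params$K1 / den)
  out[bad] <- NA_real_
  out
}

#' Fraction of tissue glucose that is phosphorylated
#'
#' The probability that a glucose molecule entering tissue is phosphorylated
#' rather than effluxed, using the converted glucose rate constants:
#' \deqn{f = \frac{k_3/\phi}{k_2/\tau + k_3/\phi}}
#'
#' @inheritParams lumped_constant
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' phosphorylation_fraction(fdg_params(0.091, 0.128, 0.057), lc_conversion())
phosphorylation_fraction <- function(params, conv = lc_conversion()) {
  k2g <- params$k2 / conv$tau
  k3g <- params$k3 / conv$phi
  den <- k2g + k3g
  if (any(den <= 0, na.rm = TRUE)) abort("k2 + k3 must be positive for the phosphorylation fraction.")
  k3g / den
}
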