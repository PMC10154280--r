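#' Temperature-adjusted Henry's law constant
#'
#' Adjusts a gas's standard-temperature Henry's law constant H(298.15 K) to an
#' arbitrary temperature with the van 't Hoff relation
#' \deqn{H(T) = H_{298.15} \exp[B (1/T - 1/298.15)]}
#' where B = -delta_sol(H)/R is the gas's temperature-dependence constant (K).
#'
#' @param gas `"CO2"`, `"O2"`, or a [gas_solubility()] object.
#' @param temperature Temperature (vectorised).
#' @param unit `"C"` (default) or `"K"`.
#' @return Henry's law constant, mol/(kg bar).
#' @export
#' @examples
#' henry_constant("CO2", 298.15, unit = "K")  # 0.035 at the reference
#' henry_constant("CO2", 40)                  # ~0.0238 at 40 degC
henry_constant <- function(gas, temperature, unit = c("C", "K")) {
  g <- .gas_params(gas)
  t_K <- .as_kelvin(temperature, unit)
  .check_temp_range(t_K)
  g$H298 * exp(g$B * (1 / t_K - 1 / 298.15))
}

#' Density of pure water
#'
#' Quadratic approximation (fit to a tabulated 0-50 degC pure-water density
#' table shipped with the package) used for mol/kg to mol/L unit bridging.
#'
#' @param temperature_c Temperature, degC, within 0-50.
#' @return Density, kg/L.
#' @export
#' @examples
#' water_density(25)  # ~0.99706
water_density <- function(temperature_c) {
  r <- .WATER_DENSITY_RANGE_C
  if (any(temperature_c < r[1])) {
    abort(sprintf("temperature %.2f degC is below the lower bound %.0f degC.",
                  min(temperature_c), r[1]))
  }
  if (any(temperature_c > r[2])) {
    abort(sprintf("temperature %.2f degC is above the upper bound %.0f degC.",
                  max(temperature_c), r[2]))
  }
  co <- .WATER_DENSITY_COEF
  co[1] + co[2] * temperature_c + co[3] * temperature_c^2
}

#' Dissolved gas concentration at equilibrium with a headspace
#'
#' Applies Henry's law C = H P with P = mole fraction x total pressure, then
#' converts the mol/kg result to uM (mol/L scale) via the density of water at
#' the same temperature.
#'
#' @inheritParams henry_constant
#' @param mole_fraction Headspace mole fraction of the gas, in `[0, 1]`
#'   (e.g. 400e-6 for 400 ppm CO2).
#' @param total_pressure Total pressure, Pa. Default 101,325 Pa.
#' @return Dissolved concentration, uM.
#' @export
#' @examples
#' dissolved_concentration("CO2", 400e-6, 40)  # ~9.6 uM
dissolved_concentration <- function(gas, mole_fraction, temperature,
                                    unit = c("C", "K"), total_pressure = 101325) {
  if (any(mole_fraction < 0) || any(mole_fraction > 1)) {
    abort("`mole_fraction` must lie in [0, 1].")
  }
  t_K <- .as_kelvin(temperature, match.arg(unit))
  H <- henry_constant(gas, t_K, unit = "K")
  p_bar <- mole_fraction * total_pressure / 1e5
  mol_per_kg <- H * p_bar
  mol_per_kg * water_density(t_K - 273.15) * 1e6
}

#' Equilibrium partial pressure of a dissolved gas
#'
#' Inverse of [dissolved_concentration()]: the headspace partial pressure in
#' equilibrium with a dissolved concentration, used to move Michaelis constants
#' between liquid-phase (uM) and gas-phase (ubar/mbar) forms.
#'
#' @inheritParams henry_constant
#' @param concentration_uM Dissolved concentration, uM (>= 0).
#' @return Partial pressure, ubar.
#' @export
#' @examples
#' partial_pressure("CO2", 3.3, 298.15, unit = "K")  # ~94.6 ubar
partial_pressure <- function(gas, concentration_uM, temperature,
                             unit = c("C", "K")) {
  if (any(concentration_uM < 0)) abort("`concentration_uM` must be >= 0.")
  t_K <- .as_kelvin(temperature, match.arg(unit))
  H <- henry_constant(gas, t_K, unit = "K")
  mol_per_kg <- concentration_uM / 1e6 / water_density(t_K - 273.15)
  (mol_per_kg / H) * 1e6
}
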