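# Shared range check for Q10 adjustment targets. Published kinetics sit at a
# 25 degC reference and the Q10 framework only extrapolates upward.
.check_adjust_temp <- function(temperature_c) {
  if (any(temperature_c < 25)) {
    abort(paste("Q10 adjustment below the 25 degC reference is unsupported:",
                "the temperature-response coefficients describe warming only."))
  }
  if (any(temperature_c > 45)) {
    abort(sprintf("temperature %.1f degC is above the upper bound 45 degC.",
                  max(temperature_c)))
  }
  invisible(temperature_c)
}

#' Temperature-adjust rubisco CO2/O2 specificity
#'
#' Applies the Q10 rule Parameter(T) = Parameter(25 degC) * Q10^((T - 25)/10)
#' to liquid-phase specificity, piecewise over the two published base
#' temperatures: the 25 degC coefficient covers 25-35 degC and the 35 degC
#' coefficient covers 35-45 degC, so e.g. S(40) = S(25) * q25 * q35^0.5.
#'
#' @param sco CO2/O2 specificity at 25 degC (molar/molar, liquid phase).
#' @param temperature_c Target temperature, degC, in `[25, 45]`.
#' @param q10 A [q10_set()].
#' @return Adjusted specificity (dimensionless), vectorised.
#' @export
#' @examples
#' adjust_specificity(238.1, 40)  # ~112.5
adjust_specificity <- function(sco, temperature_c, q10 = q10_set()) {
  .check_adjust_temp(temperature_c)
  lower <- pmin(temperature_c, 35)
  upper <- pmax(temperature_c, 35)
  sco * q10$q10_sco_25^((lower - 25) / 10) * q10$q10_sco_35^((upper - 35) / 10)
}

#' Temperature-adjust a Michaelis constant with gas-phase Q10 scaling
#'
#' The published Q10 coefficients for Kc and Ko describe partial-pressure
#' (ubar/mbar) forms, so the adjustment converts the liquid-phase constant to a
#' partial pressure at the 25 degC reference (Henry's law at 25 degC), applies
#' Q10^((T - 25)/10), and converts back to uM at the target temperature.
#'
#' @param k_uM Michaelis constant at 25 degC, uM.
#' @param gas `"CO2"`, `"O2"`, or a [gas_solubility()] object.
#' @param temperature_c Target temperature, degC, in `[25, 45]`.
#' @param q10 Scalar Q10 coefficient for this constant's gas-phase form.
#' @return A tibble with columns `k_uM` (liquid phase at T) and `k_ubar`
#'   (gas-phase form at T, ubar).
#' @export
#' @examples
#' adjust_michaelis(3.3, "CO2", 40, q10 = 2.24)  # ~7.5 uM, ~317 ubar
adjust_michaelis <- function(k_uM, gas, temperature_c, q10) {
  if (any(k_uM <= 0)) abort("`k_uM` must be > 0.")
  if (!is.numeric(q10) || length(q10) != 1 || q10 <= 0) {
    abort("`q10` must be a single positive number.")
  }
  .check_adjust_temp(temperature_c)
  k_ubar_25 <- partial_pressure(gas, k_uM, 25, unit = "C")
  k_ubar_T <- k_ubar_25 * q10^((temperature_c - 25) / 10)
  # back to uM at T: ubar -> bar -> mol/kg -> mol/L -> uM
  H_T <- henry_constant(gas, temperature_c, unit = "C")
  k_uM_T <- (k_ubar_T / 1e6) * H_T * water_density(temperature_c) * 1e6
  tibble(k_uM = k_uM_T, k_ubar = k_ubar_T)
}

#' Temperature-adjust a set of rubisco kinetic parameter sets
#'
#' Applies [adjust_specificity()] to each species' specificity and
#' [adjust_michaelis()] to its Kc (CO2, Q10 in ubar) and Ko (O2, Q10 in mbar),
#' returning both liquid-phase and gas-phase forms.
#'
#' @param kinetics Data frame with columns `species`, `Sc_o`, `Kc_uM`, `Ko_uM`
#'   (25 degC reference values), e.g. [rubisco_cyanidiales()].
#' @param temperature_c Target temperature, degC, in `[25, 45]`.
#' @param q10 A [q10_set()].
#' @return A tibble with columns `species`, `temperature_c`, `Sc_o_T`,
#'   `Kc_uM_T`, `Ko_uM_T`, `Kc_ubar_T`, `Ko_mbar_T`.
#' @export
#' @examples
#' rubisco_cyanidiales() |> adjust_kinetics(40)
adjust_kinetics <- function(kinetics, temperature_c, q10 = q10_set()) {
  need <- c("species", "Sc_o", "Kc_uM", "Ko_uM")
  missing_cols <- setdiff(need, names(kinetics))
  if (length(missing_cols)) {
    abort(paste("`kinetics` is missing column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  kc <- adjust_michaelis(kinetics$Kc_uM, "CO2", temperature_c, q10$q10_kc_ubar)
  ko <- adjust_michaelis(kinetics$Ko_uM, "O2", temperature_c, q10$q10_ko_mbar)
  tibble(
    species = kinetics$species,
    temperature_c = temperature_c,
    Sc_o_T = adjust_specificity(kinetics$Sc_o, temperature_c, q10),
    Kc_uM_T = kc$k_uM,
    Ko_uM_T = ko$k_uM,
    Kc_ubar_T = kc$k_ubar,
    Ko_mbar_T = ko$k_ubar / 1000
  )
}

#' Maximal carboxylation rate from the coupled NADH assay
#'
#' Converts the RuBP-dependent rate of NADH consumption (monitored as the
#' decline of absorbance at 340 nm) to a chlorophyll-normalised carboxylation
#' rate, using the NADH extinction coefficient and the 1:4
#' carboxylation:NADH-consumption stoichiometry of the coupled assay.
#'
#' @param abs_slope Magnitude of the RuBP-dependent A340 decline, Abs/s (>= 0).
#' @param cuvette_volume_mL Assay volume, mL.
#' @param chl_mass_ug Chlorophyll a in the assayed extract, ug.
#' @param path_cm Cuvette path length, cm. Default 1.
#' @param epsilon NADH extinction coefficient, Abs340 mM^-1 cm^-1. Default 6.22.
#' @param stoichiometry NADH consumed per carboxylation. Default 4.
#' @return Carboxylation rate, pmol CO2 ug Chl a^-1 s^-1.
#' @export
#' @examples
#' vcmax_from_nadh_assay(0.00622, cuvette_volume_mL = 1, chl_mass_ug = 1)  # 250
vcmax_from_nadh_assay <- function(abs_slope, cuvette_volume_mL, chl_mass_ug,
                                  path_cm = 1, epsilon = 6.22,
                                  stoichiometry = 4) {
  if (any(abs_slope < 0)) abort("`abs_slope` must be >= 0 (use the magnitude).")
  if (any(chl_mass_ug <= 0)) abort("`chl_mass_ug` must be > 0.")
  if (any(path_cm <= 0) || any(cuvette_volume_mL <= 0)) {
    abort("`path_cm` and `cuvette_volume_mL` must be > 0.")
  }
  nadh_mM_per_s <- abs_slope / (epsilon * path_cm)
  # mM x mL = umol; /stoichiometry NADH per carboxylation; pmol per ug Chl a
  co2_umol_per_s <- nadh_mM_per_s * cuvette_volume_mL / stoichiometry
  co2_umol_per_s * 1e6 / chl_mass_ug
}

#' Chlorophyll a concentration of a methanol extract
#'
#' Linear spectrophotometric estimate with a turbidity correction at 720 nm:
#' coefficient x (A_peak - A_720) x dilution. The default coefficient is the
#' published value for chlorophyll-a-only extracts in methanol (red-algal and
#' cyanobacterial pigment composition), 12.9447 ug/mL per absorbance unit at
#' the 665 nm peak; supply your own for other solvents or peaks.
#'
#' @param a_peak Absorbance at the chlorophyll a peak.
#' @param a720 Absorbance at 720 nm (turbidity correction); must not exceed
#'   `a_peak`, otherwise 0 is returned with a warning.
#' @param coefficient ug/mL per absorbance unit. Default 12.9447.
#' @param dilution Dilution factor applied before reading. Default 1.
#' @return Chlorophyll a, ug/mL.
#' @export
#' @examples
#' chlorophyll_a_methanol(0.5, 0.1, coefficient = 13)  # 5.2
chlorophyll_a_methanol <- function(a_peak, a720, coefficient = 12.9447,
                                   dilution = 1) {
  if (any(a720 < 0)) abort("`a720` must be >= 0.")
  diff <- a_peak - a720
  if (any(diff < 0)) {
    warn("`a_peak` < `a720` for some readings; returning 0 for those.")
    diff <- pmax(diff, 0)
  }
  coefficient * diff * dilution
}
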