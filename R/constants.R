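#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Temperature validity range for gas-solubility conversions (K)
.TEMP_RANGE_K <- c(273.15, 333.15)

# Water-density quadratic (kg/L as a function of deg C), least-squares fit to the
# packaged 0-50 degC pure-water density table (inst/extdata/water_density.csv).
.WATER_DENSITY_COEF <- c(1.00000909090909, 6.41212121213626e-06, -4.96969696969721e-06)
.WATER_DENSITY_RANGE_C <- c(0, 50)

.extdata <- function(file) {
  system.file("extdata", file, package = "phycogas", mustWork = TRUE)
}

#' Packaged Henry's law solubility constants
#'
#' Henry's law constants at 298.15 K, in mol/(kg bar), together with the
#' van 't Hoff temperature-dependence constant B = -delta_sol(H)/R in kelvin,
#' for the two gases handled by the package.
#'
#' @return A tibble with columns `gas`, `H298` (mol/(kg bar)) and `B` (K).
#' @export
#' @examples
#' gas_constants()
gas_constants <- function() {
  raw <- jsonlite::read_json(.extdata("gas_solubility.json"))
  tibble(
    gas = names(raw),
    H298 = unname(purrr::map_dbl(raw, "H298")),
    B = unname(purrr::map_dbl(raw, "B"))
  )
}

#' Define a gas solubility parameter set
#'
#' @param gas_name Label for the gas.
#' @param H298 Henry's law constant at 298.15 K, mol/(kg bar). Must be > 0.
#' @param B van 't Hoff temperature-dependence constant, K. Must be > 0.
#' @return A list of class `gas_solubility`.
#' @export
gas_solubility <- function(gas_name, H298, B) {
  if (!is.numeric(H298) || H298 <= 0) abort("`H298` must be a positive number.")
  if (!is.numeric(B) || B <= 0) abort("`B` must be a positive number.")
  structure(list(gas_name = gas_name, H298 = H298, B = B),
            class = "gas_solubility")
}

# Resolve a gas argument ("CO2"/"O2", or a gas_solubility object) to parameters.
.gas_params <- function(gas) {
  if (inherits(gas, "gas_solubility")) return(gas)
  if (is.character(gas) && length(gas) == 1) {
    tab <- gas_constants()
    hit <- match(gas, tab$gas)
    if (is.na(hit)) {
      abort(sprintf("Unknown gas '%s'; packaged gases are %s.",
                    gas, paste(tab$gas, collapse = ", ")))
    }
    return(gas_solubility(tab$gas[hit], tab$H298[hit], tab$B[hit]))
  }
  abort("`gas` must be \"CO2\", \"O2\", or a gas_solubility() object.")
}

# Convert a temperature to kelvin given an explicit unit flag.
.as_kelvin <- function(temperature, unit = c("C", "K")) {
  unit <- match.arg(unit)
  if (unit == "C") temperature + 273.15 else temperature
}

.check_temp_range <- function(t_K, range = .TEMP_RANGE_K, what = "temperature") {
  if (any(t_K < range[1])) {
    abort(sprintf("%s %.2f K is below the lower bound %.2f K.",
                  what, min(t_K), range[1]))
  }
  if (any(t_K > range[2])) {
    abort(sprintf("%s %.2f K is above the upper bound %.2f K.",
                  what, max(t_K), range[2]))
  }
  invisible(t_K)
}

#' Rubisco kinetic parameters of thermophilic Cyanidiales
#'
#' Packaged kinetic parameter sets for the rubiscos of three thermophilic red
#' algae: CO2/O2 specificity (molar/molar, liquid phase), the Michaelis
#' constant for CO2 (uM), and the Michaelis constant for O2 (uM; a single
#' published value, from *Galdieria sulphuraria*, shared across sets). All
#' values refer to a 25 degC reference temperature.
#'
#' @return A tibble with columns `species`, `Sc_o`, `Kc_uM`, `Ko_uM`, `T_ref_C`.
#' @export
#' @examples
#' rubisco_cyanidiales()
rubisco_cyanidiales <- function() {
  as_tibble(jsonlite::fromJSON(.extdata("rubisco_kinetics.json")))
}

#' Default Q10 temperature coefficients for rubisco kinetics
#'
#' Q10 coefficients describing how each rubisco kinetic parameter responds to a
#' 10 degC temperature increase: two base temperatures for liquid-phase
#' specificity (25 and 35 degC), and single coefficients for Kc (applied in
#' ubar, gas phase) and Ko (applied in mbar, gas phase).
#'
#' @param q10_sco_25,q10_sco_35 Q10 for CO2/O2 specificity based at 25 and
#'   35 degC respectively (dimensionless, < 1: specificity declines with
#'   warming).
#' @param q10_kc_ubar Q10 for Kc expressed in ubar.
#' @param q10_ko_mbar Q10 for Ko expressed in mbar.
#' @return A list of class `q10_set`.
#' @export
q10_set <- function(q10_sco_25 = 0.60, q10_sco_35 = 0.62,
                    q10_kc_ubar = 2.24, q10_ko_mbar = 1.63) {
  vals <- c(q10_sco_25, q10_sco_35, q10_kc_ubar, q10_ko_mbar)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All Q10 coefficients must be positive and finite.")
  }
  structure(list(q10_sco_25 = q10_sco_25, q10_sco_35 = q10_sco_35,
                 q10_kc_ubar = q10_kc_ubar, q10_ko_mbar = q10_ko_mbar),
            class = "q10_set")
}

#' Canonical dissolved oxygen concentrations
#'
#' Dissolved O2 concentrations used throughout the compensation-point
#' modelling, tabulated for the oxygen atmospheres and temperatures of the
#' gas-exchange experiments. `mode = "canonical"` (the default for all
#' compensation-point work) returns the canonical published values; `mode =
#' "physics"` recomputes each concentration from Henry's law at the stated
#' temperature. The two differ by up to ~8% because the provenance of the
#' canonical values' final rounding is not recorded; see the methods vignette.
#'
#' @param o2_percent Oxygen percentage of the headspace atmosphere (2, 21, 40).
#' @param temperature_c Water temperature, degC.
#' @param mode `"canonical"` for the canonical tabulated values, `"physics"` to
#'   recompute from Henry's law.
#' @param total_pressure Total pressure, Pa (physics mode only).
#' @return Dissolved O2, uM (vectorised over `o2_percent`/`temperature_c`).
#' @export
#' @examples
#' dissolved_o2(c(2, 21, 40), 40)
#' dissolved_o2(21, 40, mode = "physics")
dissolved_o2 <- function(o2_percent, temperature_c, mode = c("canonical", "physics"),
                         total_pressure = 101325) {
  mode <- match.arg(mode)
  if (mode == "physics") {
    return(dissolved_concentration("O2", o2_percent / 100,
                                   temperature = temperature_c, unit = "C",
                                   total_pressure = total_pressure))
  }
  canon <- data.frame(
    o2_percent = c(2, 21, 40, 21),
    temperature_c = c(40, 40, 40, 30),
    o2_uM = c(20, 209, 398, 251)
  )
  n <- max(length(o2_percent), length(temperature_c))
  o2_percent <- rep_len(o2_percent, n)
  temperature_c <- rep_len(temperature_c, n)
  key <- paste(o2_percent, temperature_c)
  hit <- match(key, paste(canon$o2_percent, canon$temperature_c))
  if (any(is.na(hit))) {
    abort(paste0(
      "No canonical dissolved O2 value for (",
      paste(key[is.na(hit)], collapse = "), ("),
      "); use mode = \"physics\" to compute one from Henry's law."
    ))
  }
  canon$o2_uM[hit]
}

#' Default ratio of respiration in the light to maximal carboxylation
#'
#' The ratio R_L/Vcmax used in compensation-point calculations, as estimated
#' from light-response measurements: 0.13 at 40 degC and 0.07 at 30 degC.
#'
#' @param temperature_c Temperature, degC (40 or 30).
#' @return Dimensionless ratio.
#' @export
rl_ratio_default <- function(temperature_c) {
  out <- ifelse(temperature_c == 40, 0.13,
                ifelse(temperature_c == 30, 0.07, NA_real_))
  if (any(is.na(out))) {
    abort("No default R_L/Vcmax ratio at this temperature; supply `rl_ratio`.")
  }
  out
}
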