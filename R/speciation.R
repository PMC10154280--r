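# Carbonic acid dissociation constants, mol/kg, free hydrogen-ion scale,
# activity coefficients ~ 1 (pure-water assumption).
#
# "plummer": Plummer & Busenberg (1982) zero-ionic-strength constants.
# "lueker":  Lueker et al. (2000) evaluated at salinity 0 -- the default
#            constant set of the widely used carbonate-chemistry packages this
#            module replaces, extrapolated to fresh water. Kept as the default
#            because the package's pH 2 / pH 6 interpretation layer is
#            calibrated against results computed that way; see the methods
#            vignette for the ~0.3-unit pK1 consequences.
.k1k2 <- function(t_K, formulation = c("lueker", "plummer")) {
  formulation <- match.arg(formulation)
  if (formulation == "plummer") {
    log10_K1 <- -356.3094 - 0.06091964 * t_K + 21834.37 / t_K +
      126.8339 * log10(t_K) - 1684915 / t_K^2
    log10_K2 <- -107.8871 - 0.03252849 * t_K + 5151.79 / t_K +
      38.92561 * log10(t_K) - 563713.9 / t_K^2
    list(K1 = 10^log10_K1, K2 = 10^log10_K2)
  } else {
    pK1 <- 3633.86 / t_K - 61.2172 + 9.67770 * log(t_K)
    pK2 <- 471.78 / t_K + 25.929 - 3.16967 * log(t_K)
    list(K1 = 10^-pK1, K2 = 10^-pK2)
  }
}

#' Carbonate-system equilibrium constants for fresh water
#'
#' First and second dissociation constants of carbonic acid (mol/kg) and the
#' CO2 solubility constant K0 (mol/(kg bar), from [henry_constant()]), at a
#' given temperature, for salinity-zero water with unit activity coefficients.
#' Two published formulations are available; see the methods vignette for why
#' both are shipped and how they differ.
#'
#' @param temperature Temperature (vectorised).
#' @param unit `"C"` (default) or `"K"`.
#' @param formulation `"lueker"` (default) or `"plummer"`.
#' @return A tibble with columns `temperature_K`, `formulation`, `K0`, `K1`,
#'   `K2`, `pK1`, `pK2`.
#' @export
#' @examples
#' carbonate_constants(25, formulation = "plummer")  # pK1 ~ 6.35
carbonate_constants <- function(temperature, unit = c("C", "K"),
                                formulation = c("lueker", "plummer")) {
  formulation <- match.arg(formulation)
  t_K <- .as_kelvin(temperature, match.arg(unit))
  .check_temp_range(t_K)
  ks <- .k1k2(t_K, formulation)
  tibble(
    temperature_K = t_K,
    formulation = formulation,
    K0 = henry_constant("CO2", t_K, unit = "K"),
    K1 = ks$K1,
    K2 = ks$K2,
    pK1 = -log10(ks$K1),
    pK2 = -log10(ks$K2)
  )
}

#' Dissolved inorganic carbon speciation at fixed headspace pCO2
#'
#' Computes the CO2(aq), bicarbonate and carbonate pools of water in
#' equilibrium with a fixed CO2 partial pressure, across pH. Under this
#' convention CO2(aq) is set by Henry's law alone and is therefore identical
#' across pH at a given temperature, while the ionic pools grow with pH:
#' HCO3- = CO2(aq) K1/[H+], CO3^2- = HCO3- K2/[H+]. Concentrations are
#' computed on the mol/kg scale and reported in uM via the density of water.
#'
#' @param pco2_ppm Headspace CO2, umol/mol (>= 0).
#' @param ph pH (free hydrogen-ion scale), in (0, 14); vectorised.
#' @param temperature Temperature (vectorised with `ph`).
#' @param unit `"C"` (default) or `"K"`.
#' @param total_pressure Total pressure, Pa. Default 101,325.
#' @param formulation Constant set, see [carbonate_constants()].
#' @return A tibble with columns `pco2_ppm`, `ph`, `temperature_c`,
#'   `co2_aq_uM`, `hco3_uM`, `co3_uM`, `dic_uM`, `hco3_fraction`.
#' @export
#' @examples
#' speciate_from_pco2(400, ph = c(2, 6), temperature = 40)
speciate_from_pco2 <- function(pco2_ppm, ph, temperature, unit = c("C", "K"),
                               total_pressure = 101325,
                               formulation = c("lueker", "plummer")) {
  if (any(pco2_ppm < 0)) abort("`pco2_ppm` must be >= 0.")
  if (any(ph <= 0) || any(ph >= 14)) abort("`ph` must lie in (0, 14).")
  t_K <- .as_kelvin(temperature, match.arg(unit))
  k <- carbonate_constants(t_K, unit = "K", formulation = formulation)
  h <- 10^(-ph)
  p_bar <- pco2_ppm * 1e-6 * total_pressure / 1e5
  co2_molkg <- k$K0 * p_bar
  hco3_molkg <- co2_molkg * k$K1 / h
  co3_molkg <- hco3_molkg * k$K2 / h
  to_uM <- water_density(t_K - 273.15) * 1e6
  dic <- co2_molkg + hco3_molkg + co3_molkg
  tibble(
    pco2_ppm = pco2_ppm,
    ph = ph,
    temperature_c = t_K - 273.15,
    co2_aq_uM = co2_molkg * to_uM,
    hco3_uM = hco3_molkg * to_uM,
    co3_uM = co3_molkg * to_uM,
    dic_uM = dic * to_uM,
    hco3_fraction = ifelse(dic > 0, hco3_molkg / dic, NA_real_)
  )
}

#' Bicarbonate fraction of the dissolved inorganic carbon pool
#'
#' Fraction of DIC present as HCO3- under the fixed-CO2(aq) convention of
#' [speciate_from_pco2()]; independent of the pCO2 level.
#'
#' @inheritParams speciate_from_pco2
#' @return Fraction in `[0, 1]`, vectorised over `ph`/`temperature`.
#' @export
#' @examples
#' bicarbonate_fraction(c(2, 6), 40)
bicarbonate_fraction <- function(ph, temperature, unit = c("C", "K"),
                                 formulation = c("lueker", "plummer")) {
  if (any(ph <= 0) || any(ph >= 14)) abort("`ph` must lie in (0, 14).")
  t_K <- .as_kelvin(temperature, match.arg(unit))
  k <- carbonate_constants(t_K, unit = "K", formulation = formulation)
  h <- 10^(-ph)
  r1 <- k$K1 / h
  r2 <- r1 * k$K2 / h
  r1 / (1 + r1 + r2)
}

#' Inorganic carbon pool accessible to an uptake model
#'
#' The inorganic carbon a cell can draw on given its uptake capabilities:
#' CO2(aq) always, plus the bicarbonate pool when the organism can take up
#' HCO3- (carbonate is never considered accessible). A bicarbonate-capable
#' organism at a pH where HCO3- roughly equals CO2(aq) therefore sees about
#' twice the accessible pool of a CO2-only organism.
#'
#' @param state Data frame with columns `co2_aq_uM` and `hco3_uM`, e.g. from
#'   [speciate_from_pco2()].
#' @param bicarbonate Logical (or 0/1): can the organism take up bicarbonate?
#' @return `state` with an added `accessible_ci_uM` column.
#' @export
#' @examples
#' speciate_from_pco2(400, c(2, 6), 40) |> accessible_ci(bicarbonate = TRUE)
accessible_ci <- function(state, bicarbonate = FALSE) {
  need <- c("co2_aq_uM", "hco3_uM")
  if (!all(need %in% names(state))) {
    abort("`state` must have columns co2_aq_uM and hco3_uM.")
  }
  beta <- as.numeric(bicarbonate)
  if (!all(beta %in% c(0, 1))) abort("`bicarbonate` must be TRUE/FALSE (or 0/1).")
  dplyr::mutate(as_tibble(state),
                accessible_ci_uM = .data$co2_aq_uM + beta * .data$hco3_uM)
}
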