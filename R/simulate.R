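# Seed-splitting rule: replicate i of a simulation seeded with `seed` draws
# from its own stream seeded with split_seed(seed, i), so changing the
# replicate count never reshuffles earlier replicates.
split_seed <- function(seed, i) {
  (as.numeric(seed) + 1000003 * i) %% 2147483647
}

.check_noise <- function(noise_sd) {
  if (any(noise_sd < 0)) abort("`noise_sd` must be >= 0.")
}

#' Simulate CO2-response curves with known ground truth
#'
#' Generates replicate CO2-response curves from the offset Michaelis-Menten
#' model
#' \deqn{A(C) = (A_{max} + R_L) \frac{C}{K_m + C} - R_L + \epsilon}
#' with additive Gaussian noise. The offset form saturates at Amax, respires
#' R_L in the dark, and crosses zero at the analytic compensation point
#' Gamma = Km R_L / Amax, so a single simulated curve carries meaningful
#' targets for both the Michaelis-Menten fit and the compensation-point fit.
#'
#' @param km True Michaelis constant, in driver units (headspace ppm).
#'   Default 150.
#' @param amax True maximal net assimilation, pmol CO2 ug Chl a^-1 s^-1.
#'   Default 35 (a typical 40 degC cellular value).
#' @param rl True respiration in the light, same units. Default
#'   `0.13 * amax` (the 40 degC R_L/Amax ratio).
#' @param noise_sd Additive Gaussian noise SD, flux units. Default
#'   `0.05 * amax`.
#' @param driver_grid Headspace CO2 levels, ppm.
#' @param n_replicates Number of replicate curves. Default 3.
#' @param seed Master seed; replicate i uses its own derived stream.
#' @param temperature_c,o2_percent,ph,sample_id Metadata carried into the
#'   output records.
#' @return A tibble with columns `sample_id`, `replicate`, `temperature_c`,
#'   `o2_percent`, `ph`, `driver` (ppm), `assimilation`; ground truth (km,
#'   amax, rl, gamma = km*rl/amax, noise_sd, seed) in attribute `truth`.
#' @export
#' @examples
#' sim <- simulate_co2_response(noise_sd = 0, n_replicates = 1)
#' attr(sim, "truth")$gamma
simulate_co2_response <- function(km = 150, amax = 35, rl = 0.13 * amax,
                                  noise_sd = 0.05 * amax,
                                  driver_grid = c(20, 50, 100, 200, 400, 700, 1000, 1400),
                                  n_replicates = 3, seed = 1,
                                  temperature_c = 40, o2_percent = 21, ph = 2,
                                  sample_id = "synthetic") {
  if (km <= 0 || amax <= 0) abort("`km` and `amax` must be > 0.")
  if (rl < 0) abort("`rl` must be >= 0.")
  .check_noise(noise_sd)
  curves <- purrr::map(seq_len(n_replicates), function(i) {
    set.seed(split_seed(seed, i))
    mean_a <- (amax + rl) * driver_grid / (km + driver_grid) - rl
    tibble(
      sample_id = sample_id, replicate = i,
      temperature_c = temperature_c, o2_percent = o2_percent, ph = ph,
      driver = driver_grid,
      assimilation = mean_a + stats::rnorm(length(driver_grid), 0, noise_sd)
    )
  })
  out <- dplyr::bind_rows(curves)
  attr(out, "truth") <- list(km = km, amax = amax, rl = rl,
                             gamma = km * rl / amax,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate light-response curves for Kok-method testing
#'
#' Net assimilation rises linearly with incident light, A(I) = phi I - R_L, up
#' to `i_break`, then saturates smoothly (continuously differentiable
#' exponential approach to `amax`). The Kok window sits inside the linear
#' segment, so a noise-free Kok fit recovers R_L exactly.
#'
#' @param phi True initial slope (quantum-efficiency proxy), flux per
#'   umol m^-2 s^-1. Default 0.05.
#' @param rl True respiration in the light, flux units. Default 4.55.
#' @param amax Saturating net assimilation. Default 35.
#' @param i_break Incident light at which the linear segment ends. Default 150.
#' @param light_grid Incident light levels, umol m^-2 s^-1.
#' @inheritParams simulate_co2_response
#' @return A tibble with columns `sample_id`, `replicate`, `temperature_c`,
#'   `driver` (incident light), `assimilation`; truth (phi, rl, amax, i_break,
#'   noise_sd, seed) in attribute `truth`.
#' @export
simulate_light_response <- function(phi = 0.05, rl = 4.55, amax = 35,
                                    i_break = 150,
                                    light_grid = c(10, 20, 30, 50, 100, 200, 400, 800, 1500, 2000),
                                    noise_sd = 0, n_replicates = 1, seed = 1,
                                    temperature_c = 40,
                                    sample_id = "synthetic") {
  if (phi <= 0 || amax <= 0 || i_break <= 0) {
    abort("`phi`, `amax` and `i_break` must be > 0.")
  }
  if (rl < 0) abort("`rl` must be >= 0.")
  .check_noise(noise_sd)
  a_break <- phi * i_break - rl
  headroom <- amax - a_break
  if (headroom <= 0) {
    abort("`amax` must exceed the linear segment's value at `i_break`.")
  }
  mean_a <- function(I) {
    ifelse(I <= i_break,
           phi * I - rl,
           amax - headroom * exp(-phi * (I - i_break) / headroom))
  }
  curves <- purrr::map(seq_len(n_replicates), function(i) {
    set.seed(split_seed(seed, i))
    tibble(
      sample_id = sample_id, replicate = i, temperature_c = temperature_c,
      driver = light_grid,
      assimilation = mean_a(light_grid) +
        stats::rnorm(length(light_grid), 0, noise_sd)
    )
  })
  out <- dplyr::bind_rows(curves)
  attr(out, "truth") <- list(phi = phi, rl = rl, amax = amax,
                             i_break = i_break, noise_sd = noise_sd,
                             seed = seed)
  out
}

#' Simulate replicate compensation-point oxygen responses
#'
#' Generates measured-style (replicate, O2, Gamma) tables from a linear oxygen
#' response Gamma(O) = slope O + intercept + noise. When `kinetics` is
#' supplied, each replicate's slope and intercept come from a
#' kinetics-calculated combination (cycling through the [gamma_grid()]
#' combinations), with `attenuation` multiplying the slope to emulate a
#' carbon-concentrating mechanism damping the oxygen sensitivity.
#'
#' @param slope_true True slope, pM CO2 / uM O2 (ignored when `kinetics` is
#'   supplied). Default 5425.
#' @param intercept_true True intercept, uM. Default 0.56.
#' @param o_levels Dissolved O2 levels per replicate, uM.
#' @param kinetics Optional 25 degC kinetics table; see [gamma_grid()].
#' @param attenuation Slope multiplier in (0, 1] applied to kinetic slopes.
#' @param temperature_c Assay temperature for the kinetic route. Default 40.
#' @param rl_ratio R_L/Vcmax for the kinetic route; default by temperature.
#' @param noise_sd Gaussian noise SD on Gamma, uM. Default 0.1.
#' @param n_replicates Number of replicates. Default 6.
#' @param seed Master seed.
#' @return A tibble with columns `replicate`, `o_uM`, `gamma_uM`; per-replicate
#'   true slopes (pM/uM) and intercepts in attribute `truth`.
#' @export
simulate_oxygen_response <- function(slope_true = 5425, intercept_true = 0.56,
                                     o_levels = c(20, 209, 398),
                                     kinetics = NULL, attenuation = 1,
                                     temperature_c = 40, rl_ratio = NULL,
                                     noise_sd = 0.1, n_replicates = 6,
                                     seed = 1) {
  .check_noise(noise_sd)
  if (attenuation <= 0 || attenuation > 1) {
    abort("`attenuation` must lie in (0, 1].")
  }
  if (!is.null(kinetics)) {
    grid <- gamma_grid(kinetics, temperature_c = temperature_c,
                       o_levels = o_levels, rl_ratio = rl_ratio)
    idx <- ((seq_len(n_replicates) - 1) %% nrow(grid$slopes)) + 1
    slopes <- grid$slopes$analytic_slope_pM_per_uM[idx] * attenuation
    intercepts <- grid$slopes$intercept_uM[idx]
  } else {
    slopes <- rep(slope_true * attenuation, n_replicates)
    intercepts <- rep(intercept_true, n_replicates)
  }
  rows <- purrr::map(seq_len(n_replicates), function(i) {
    set.seed(split_seed(seed, i))
    tibble(
      replicate = i,
      o_uM = o_levels,
      gamma_uM = slopes[i] * 1e-6 * o_levels + intercepts[i] +
        stats::rnorm(length(o_levels), 0, noise_sd)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- list(slope_pM_per_uM = slopes,
                             intercept_uM = intercepts,
                             attenuation = attenuation,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a paired pH 2 / pH 6 CO2-response experiment
#'
#' Generates paired response curves in which the physiological driver is the
#' *accessible* inorganic carbon pool at each pH: CO2(aq) alone for a
#' CO2-only organism, CO2(aq) + HCO3- for a bicarbonate-capable one (see
#' [accessible_ci()]). Because CO2(aq) per headspace ppm is pH-independent
#' while bicarbonate roughly equals CO2(aq) at pH 6, a bicarbonate-capable
#' organism's apparent Km in headspace-ppm units is about half as large at
#' pH 6 as at pH 2; a CO2-only organism shows equal apparent Km at both pH.
#'
#' @param km_ci True Michaelis constant in accessible-Ci units, uM. Default 4.8
#'   (about 200 ppm of CO2(aq) at 40 degC).
#' @param bicarbonate Can the simulated organism take up bicarbonate?
#' @param ph_pair The two assay pH values. Default `c(2, 6)`.
#' @param ppm_grid Headspace CO2 levels, ppm.
#' @param formulation Carbonate-constant set, see [carbonate_constants()].
#' @inheritParams simulate_co2_response
#' @return A tibble of curves at both pH (columns as in
#'   [simulate_co2_response()]); truth (km_ci, apparent km in ppm per pH,
#'   their ratio, amax, rl, beta, noise_sd, seed) in attribute `truth`.
#' @export
simulate_ph_experiment <- function(km_ci = 4.8, amax = 35, rl = 0.13 * amax,
                                   bicarbonate = TRUE, ph_pair = c(2, 6),
                                   ppm_grid = c(20, 50, 100, 200, 400, 700, 1000, 1400),
                                   noise_sd = 0.05 * amax, n_replicates = 3,
                                   seed = 1, temperature_c = 40,
                                   formulation = c("lueker", "plummer"),
                                   sample_id = "synthetic") {
  formulation <- match.arg(formulation)
  if (km_ci <= 0 || amax <= 0) abort("`km_ci` and `amax` must be > 0.")
  if (rl < 0) abort("`rl` must be >= 0.")
  .check_noise(noise_sd)
  beta <- as.numeric(bicarbonate)
  # accessible Ci per headspace ppm at each pH (speciation is linear in pCO2)
  per_ppm <- speciate_from_pco2(1, ph_pair, temperature_c,
                                formulation = formulation) |>
    accessible_ci(bicarbonate = bicarbonate)
  s <- per_ppm$accessible_ci_uM
  rows <- list()
  k <- 0
  for (j in seq_along(ph_pair)) {
    for (i in seq_len(n_replicates)) {
      k <- k + 1
      set.seed(split_seed(seed, (j - 1) * n_replicates + i))
      ci <- s[j] * ppm_grid
      mean_a <- (amax + rl) * ci / (km_ci + ci) - rl
      rows[[k]] <- tibble(
        sample_id = sample_id, replicate = i,
        temperature_c = temperature_c, o2_percent = 21, ph = ph_pair[j],
        driver = ppm_grid,
        assimilation = mean_a + stats::rnorm(length(ppm_grid), 0, noise_sd)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  km_ppm <- km_ci / s
  attr(out, "truth") <- list(
    km_ci = km_ci, km_ppm = stats::setNames(km_ppm, paste0("ph", ph_pair)),
    km_ratio = km_ppm[2] / km_ppm[1], amax = amax, rl = rl, beta = beta,
    noise_sd = noise_sd, seed = seed
  )
  out
}
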