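#' Headspace CO2 concentration from chamber records
#'
#' Converts aquatic-chamber instrument records to headspace CO2 concentrations.
#' The instrument reports the reference-minus-sample chamber difference
#' (`delta_co2_ppm`); the subsample-loop correction scales it by the ratio of
#' sample flow to subsample-loop flow, dC_sub = (flow / subsample_flow) * dC,
#' and the headspace concentration is the sample-chamber concentration minus
#' dC_sub (sample-chamber CO2 exceeds headspace CO2 whenever the cells draw
#' CO2 down). Negative results are replaced with zero and flagged.
#'
#' @param records Data frame with columns `reference_co2_ppm`,
#'   `delta_co2_ppm`, `flow_umol_s` and `subsample_flow_umol_s`.
#' @return `records` with added columns `headspace_co2_ppm` and
#'   `headspace_clamped` (logical). The number of clamped records is attached
#'   as attribute `n_clamped`.
#' @export
#' @examples
#' tibble::tibble(reference_co2_ppm = 400, delta_co2_ppm = 20,
#'                flow_umol_s = 400, subsample_flow_umol_s = 233) |>
#'   headspace_co2()
headspace_co2 <- function(records) {
  need <- c("reference_co2_ppm", "delta_co2_ppm", "flow_umol_s",
            "subsample_flow_umol_s")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(paste("`records` is missing column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  if (any(records$flow_umol_s <= 0) || any(records$subsample_flow_umol_s <= 0)) {
    abort("Flow rates must be > 0.")
  }
  sample_chamber <- records$reference_co2_ppm - records$delta_co2_ppm
  dc_sub <- records$flow_umol_s / records$subsample_flow_umol_s *
    records$delta_co2_ppm
  raw <- sample_chamber - dc_sub
  out <- dplyr::mutate(as_tibble(records),
                       headspace_co2_ppm = pmax(raw, 0),
                       headspace_clamped = raw < 0)
  attr(out, "n_clamped") <- sum(out$headspace_clamped)
  out
}

#' Convert a headspace-ppm response curve to dissolved concentrations
#'
#' Maps each headspace CO2 value of a response curve to the equilibrium
#' dissolved concentration via Henry's law at the curve's temperature, adding a
#' `dissolved_co2_uM` column. The mapping is strictly increasing, so curve
#' shape and point ordering are preserved.
#'
#' @param curve Data frame holding one or more response curves.
#' @param temperature_c Water temperature, degC. If NULL, taken from a
#'   `temperature_c` column of `curve`.
#' @param driver Column holding headspace CO2 in ppm; default `driver`.
#' @param total_pressure Total pressure, Pa.
#' @return `curve` with an added `dissolved_co2_uM` column.
#' @export
#' @examples
#' tibble::tibble(driver = c(100, 400), temperature_c = 40) |> to_dissolved()
to_dissolved <- function(curve, temperature_c = NULL, driver = driver,
                         total_pressure = 101325) {
  ppm <- dplyr::pull(curve, {{ driver }})
  temperature_c <- temperature_c %||% curve[["temperature_c"]]
  if (is.null(temperature_c)) {
    abort("Supply `temperature_c` or include a temperature_c column.")
  }
  uM <- dissolved_concentration("CO2", ppm * 1e-6, temperature_c, unit = "C",
                                total_pressure = total_pressure)
  dplyr::mutate(as_tibble(curve), dissolved_co2_uM = uM)
}

# Shared pull-and-check for the fit functions.
.fit_xy <- function(data, driver, response, min_points, context) {
  x <- dplyr::pull(data, {{ driver }})
  y <- dplyr::pull(data, {{ response }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_points) {
    abort(sprintf("%s needs at least %d points; got %d.",
                  context, min_points, length(x)))
  }
  list(x = x, y = y)
}

#' Fit a two-parameter Michaelis-Menten CO2-response curve
#'
#' Nonlinear least-squares fit of A = Amax C / (Km + C) to a CO2-response
#' curve (Levenberg-Marquardt), optionally restricted to points strictly below
#' a driver cutoff. 95% confidence half-intervals come from the linearised
#' parameter covariance at the optimum.
#'
#' @param data Data frame holding one response curve.
#' @param driver,response Columns holding the CO2 driver and net assimilation;
#'   defaults `driver` and `assimilation`.
#' @param max_driver Optional cutoff: only points with driver `< max_driver`
#'   are fit (as used for curves that depart from saturation kinetics at high
#'   CO2).
#' @param conf_level Confidence level for the half-intervals. Default 0.95.
#' @return An object of class `mm_fit` with elements `km`, `amax`, `ci_km`,
#'   `ci_amax` (half-widths), `se_km`, `se_amax`, `n_points_used`, `fit` and
#'   `data`. Supports [generics::tidy()], [generics::glance()] and
#'   `autoplot()`.
#' @export
#' @examples
#' curve <- tibble::tibble(driver = c(25, 50, 100, 200, 400, 800),
#'                         assimilation = 35 * driver / (150 + driver))
#' fit_michaelis_menten(curve)
fit_michaelis_menten <- function(data, driver = driver, response = assimilation,
                                 max_driver = NULL, conf_level = 0.95) {
  xy <- .fit_xy(data, {{ driver }}, {{ response }}, 3,
                "A Michaelis-Menten fit")
  if (!is.null(max_driver)) {
    keep <- xy$x < max_driver
    xy <- list(x = xy$x[keep], y = xy$y[keep])
    if (length(xy$x) < 3) {
      abort(sprintf(
        "Only %d points remain below max_driver = %g; at least 3 are required.",
        length(xy$x), max_driver))
    }
  }
  df <- data.frame(x = xy$x, y = xy$y)
  amax0 <- max(df$y)
  km0 <- df$x[which.min(abs(df$y - amax0 / 2))]
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(df$x)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ amax * x / (km + x), data = df,
                      start = list(amax = amax0, km = km0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(paste("Michaelis-Menten fit failed to converge:",
                  conditionMessage(e)))
    }
  )
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = stats::df.residual(fit))
  structure(
    list(km = unname(est["km"]), amax = unname(est["amax"]),
         se_km = unname(se["km"]), se_amax = unname(se["amax"]),
         ci_km = unname(tq * se["km"]), ci_amax = unname(tq * se["amax"]),
         conf_level = conf_level, n_points_used = nrow(df),
         fit = fit, data = df),
    class = "mm_fit"
  )
}

#' Fit the CO2 compensation point from low-CO2 response points
#'
#' Ordinary least-squares line through the response points at or below a
#' driver threshold; the compensation point is the x-intercept,
#' Gamma = -intercept/slope.
#'
#' @inheritParams fit_michaelis_menten
#' @param threshold Only points with driver `<= threshold` are used.
#'   Default 100 (ppm).
#' @return An object of class `comp_fit` with elements `gamma`, `slope`,
#'   `intercept`, `n_points_used` and `fit`.
#' @export
#' @examples
#' tibble::tibble(driver = c(20, 60, 100), assimilation = c(-2, 2, 6)) |>
#'   fit_compensation_point()  # gamma = 40
fit_compensation_point <- function(data, driver = driver,
                                   response = assimilation, threshold = 100) {
  xy <- .fit_xy(data, {{ driver }}, {{ response }}, 2,
                "A compensation-point fit")
  keep <- xy$x <= threshold
  x <- xy$x[keep]; y <- xy$y[keep]
  if (length(unique(x)) < 2) {
    abort(sprintf(
      "At least 2 distinct points at or below threshold = %g are required.",
      threshold))
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)["x"])
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  if (slope <= 0) {
    abort("Degenerate compensation-point fit: nonpositive slope in the low-CO2 window.")
  }
  structure(
    list(gamma = -intercept / slope, slope = slope, intercept = intercept,
         threshold = threshold, n_points_used = length(x), fit = fit),
    class = "comp_fit"
  )
}

#' Estimate respiration in the light by the Kok method
#'
#' Ordinary least-squares line through the low-light points of a light-response
#' curve, within a window of incident irradiance; respiration in the light
#' (R_L) is the magnitude of the extrapolated zero-light intercept, and the
#' slope is a quantum-efficiency proxy.
#'
#' @param data Data frame holding one light-response curve.
#' @param light,response Columns holding incident irradiance
#'   (umol m^-2 s^-1) and net assimilation; defaults `driver` and
#'   `assimilation`.
#' @param window Inclusive incident-light window. Default `c(10, 30)`.
#' @return An object of class `kok_fit` with elements `rl` (positive
#'   magnitude), `slope`, `intercept`, `window`, `n_points_used` and `fit`.
#' @export
#' @examples
#' tibble::tibble(driver = c(10, 20, 30), assimilation = 0.05 * driver - 3) |>
#'   fit_kok()  # rl = 3
fit_kok <- function(data, light = driver, response = assimilation,
                    window = c(10, 30)) {
  xy <- .fit_xy(data, {{ light }}, {{ response }}, 2, "A Kok fit")
  keep <- xy$x >= window[1] & xy$x <= window[2]
  x <- xy$x[keep]; y <- xy$y[keep]
  if (length(unique(x)) < 2) {
    abort(sprintf(
      "At least 2 distinct points inside the [%g, %g] light window are required.",
      window[1], window[2]))
  }
  fit <- stats::lm(y ~ x)
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  structure(
    list(rl = -intercept, slope = unname(stats::coef(fit)["x"]),
         intercept = intercept, window = window,
         n_points_used = length(x), fit = fit),
    class = "kok_fit"
  )
}

#' Replicate-level oxygen response of the measured compensation point
#'
#' Fits an ordinary least-squares compensation-point-vs-O2 line per replicate
#' and aggregates the slopes as mean +/- 2 standard errors, the summary used to
#' compare measured oxygen sensitivity with the range calculated from rubisco
#' kinetics.
#'
#' @param comp_points Data frame of measured compensation points.
#' @param replicate,o,gamma Columns holding the replicate id, dissolved O2
#'   (uM), and the compensation point (uM); defaults `replicate`, `o_uM`,
#'   `gamma_uM`.
#' @return A list of class `oxygen_response` with `per_replicate` (tibble of
#'   per-replicate slopes, pM/uM), `mean_slope_pM_per_uM`, `se_pM_per_uM`
#'   (NA with a single replicate), `ci2_pM_per_uM` (2 SE), and `n_replicates`.
#' @export
oxygen_response_analysis <- function(comp_points, replicate = replicate,
                                     o = o_uM, gamma = gamma_uM) {
  df <- dplyr::tibble(
    replicate = dplyr::pull(comp_points, {{ replicate }}),
    o = dplyr::pull(comp_points, {{ o }}),
    g = dplyr::pull(comp_points, {{ gamma }})
  )
  if (length(unique(df$o)) < 2) {
    abort("At least two distinct O2 levels are required.")
  }
  counts <- dplyr::count(df, .data$replicate)
  if (length(unique(counts$n)) > 1) {
    warn("Unbalanced design: replicates have differing numbers of O2 levels.")
  }
  per <- df |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(
      slope_pM_per_uM = stats::coef(stats::lm(g ~ o))[["o"]] * 1e6,
      n_levels = length(unique(.data$o)),
      .groups = "drop"
    )
  n <- nrow(per)
  se <- if (n > 1) stats::sd(per$slope_pM_per_uM) / sqrt(n) else NA_real_
  structure(
    list(per_replicate = per,
         mean_slope_pM_per_uM = mean(per$slope_pM_per_uM),
         se_pM_per_uM = se,
         ci2_pM_per_uM = 2 * se,
         n_replicates = n),
    class = "oxygen_response"
  )
}

#' @export
print.oxygen_response <- function(x, ...) {
  cat(sprintf("Oxygen response over %d replicate(s): slope %.0f +/- %.0f pM CO2/uM O2 (mean +/- 2 SE)\n",
              x$n_replicates, x$mean_slope_pM_per_uM,
              ifelse(is.na(x$ci2_pM_per_uM), NA, x$ci2_pM_per_uM)))
  invisible(x)
}

#' Directional Welch tests for the pH 2 vs pH 6 comparison
#'
#' Two one-sided Welch t-tests per gas-exchange parameter, formalising the
#' bicarbonate-uptake question: if cells could use bicarbonate, the apparent
#' Michaelis constant at pH 6 (where HCO3- roughly equals CO2(aq)) should be
#' about half its pH 2 value.
#'
#' * `half_mean`: H0 mu_6 = mu_2/2 against H1 mu_6 < mu_2/2, computed as a
#'   Welch test of the pH 6 sample against the pH 2 sample scaled by 0.5
#'   (variances scaled by 0.25). A large p-value means the data are
#'   incompatible with the "pH 6 is at most half" direction.
#' * `ph2_greater`: H1 mu_2 > mu_6, the plain directional comparison.
#'
#' @param params_ph2,params_ph6 Replicate-level parameter values measured at
#'   pH 2 and pH 6 (>= 2 each).
#' @param parameter Optional parameter label carried into the output.
#' @return A tibble with columns `parameter`, `test`, `alternative`,
#'   `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' ph_comparison_tests(c(200, 210, 220), c(100, 105, 110))
ph_comparison_tests <- function(params_ph2, params_ph6, parameter = "parameter") {
  if (length(params_ph2) < 2 || length(params_ph6) < 2) {
    abort("At least 2 replicates per pH group are required.")
  }
  half <- stats::t.test(params_ph6, 0.5 * params_ph2, alternative = "less")
  greater <- stats::t.test(params_ph2, params_ph6, alternative = "greater")
  tibble(
    parameter = parameter,
    test = c("half_mean", "ph2_greater"),
    alternative = c("pH6 mean < 0.5 x pH2 mean", "pH2 mean > pH6 mean"),
    statistic = c(unname(half$statistic), unname(greater$statistic)),
    df = c(unname(half$parameter), unname(greater$parameter)),
    p_value = c(half$p.value, greater$p.value)
  )
}
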