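#' CO2 compensation point from rubisco kinetics
#'
#' Evaluates the biochemical CO2 compensation point of net assimilation,
#' \deqn{\Gamma = \frac{0.5/S_{c/o} + K_c r / K_o}{1 - r} O +
#'       \frac{K_c r}{1 - r}, \quad r = R_L/V_{cmax},}
#' with all quantities in liquid-phase (uM) form. The result is exactly linear
#' in dissolved O2, so the oxygen-response slope and O-independent intercept
#' are returned alongside the evaluated compensation point.
#'
#' @param sco Temperature-adjusted CO2/O2 specificity (dimensionless).
#' @param kc_uM Temperature-adjusted Kc, uM.
#' @param ko_uM Temperature-adjusted Ko, uM.
#' @param rl_ratio r = R_L/Vcmax, in `[0, 1)`.
#' @param o_uM Dissolved O2, uM (>= 0).
#' @return A tibble with columns `o_uM`, `gamma_uM`, `slope_term` (uM CO2 per
#'   uM O2) and `intercept_term` (uM). Vectorised over all arguments.
#' @export
#' @examples
#' gamma_co2(112.5, 7.49, 589, rl_ratio = 0.13, o_uM = 209)
gamma_co2 <- function(sco, kc_uM, ko_uM, rl_ratio, o_uM) {
  if (any(rl_ratio >= 1)) {
    abort("`rl_ratio` >= 1: respiration equals or exceeds Vcmax, the compensation point is singular.")
  }
  if (any(rl_ratio < 0)) abort("`rl_ratio` must be >= 0.")
  if (any(c(sco, kc_uM, ko_uM) <= 0)) abort("Kinetic parameters must be > 0.")
  if (any(o_uM < 0)) abort("`o_uM` must be >= 0.")
  slope <- (0.5 / sco + kc_uM * rl_ratio / ko_uM) / (1 - rl_ratio)
  intercept <- kc_uM * rl_ratio / (1 - rl_ratio)
  tibble(
    o_uM = o_uM,
    gamma_uM = slope * o_uM + intercept,
    slope_term = slope,
    intercept_term = intercept
  )
}

#' Compensation-point grid over kinetic parameter combinations
#'
#' Evaluates [gamma_co2()] for every cross-combination of the supplied
#' specificity and Kc sources (with the shared Ko), after Q10 adjustment to the
#' assay temperature, at each dissolved O2 level; then fits an ordinary
#' least-squares line through (O2, Gamma) per combination to extract the
#' oxygen-response slope. Because the model is exactly linear in O2 the fitted
#' slope equals the analytic coefficient; both are recorded.
#'
#' @param kinetics Data frame of 25 degC kinetics (see [adjust_kinetics()]).
#'   Default [rubisco_cyanidiales()].
#' @param temperature_c Assay temperature, degC. Default 40.
#' @param o_levels Dissolved O2 levels, uM. Default: the canonical values for
#'   2/21/40% O2 at `temperature_c` from [dissolved_o2()] in the given `mode`.
#' @param rl_ratio R_L/Vcmax. Default [rl_ratio_default()] at `temperature_c`.
#' @param q10 A [q10_set()].
#' @param mode Passed to [dissolved_o2()] when `o_levels` is NULL.
#' @return An object of class `gamma_grid`: a list with `rows` (one row per
#'   combination x O2 level), `slopes` (per-combination OLS and analytic slopes,
#'   pM CO2 / uM O2), `slope_min`, `slope_max`, `gamma_range` (per O2 level),
#'   and the call parameters.
#' @export
#' @examples
#' g <- gamma_grid()
#' g$slope_min; g$slope_max
gamma_grid <- function(kinetics = rubisco_cyanidiales(), temperature_c = 40,
                       o_levels = NULL, rl_ratio = NULL, q10 = q10_set(),
                       mode = c("canonical", "physics")) {
  mode <- match.arg(mode)
  if (nrow(kinetics) == 0) abort("`kinetics` must have at least one row.")
  if (is.null(o_levels)) {
    o_levels <- dissolved_o2(c(2, 21, 40), temperature_c, mode = mode)
  }
  if (length(o_levels) == 0) abort("`o_levels` must be nonempty.")
  rl_ratio <- rl_ratio %||% rl_ratio_default(temperature_c)

  adj <- adjust_kinetics(kinetics, temperature_c, q10)
  ko_uM_T <- adj$Ko_uM_T[1]  # single shared Ko across combinations

  combos <- tidyr::expand_grid(
    sco_source = adj$species,
    kc_source = adj$species
  ) |>
    dplyr::mutate(
      combination = paste(.data$sco_source, "x", .data$kc_source),
      Sc_o_T = adj$Sc_o_T[match(.data$sco_source, adj$species)],
      Kc_uM_T = adj$Kc_uM_T[match(.data$kc_source, adj$species)],
      Ko_uM_T = ko_uM_T
    )

  rows <- combos |>
    tidyr::expand_grid(o_uM = o_levels) |>
    dplyr::mutate(gamma_co2(.data$Sc_o_T, .data$Kc_uM_T, .data$Ko_uM_T,
                            rl_ratio, .data$o_uM)[-1])

  ols_slope <- function(o, g) {
    if (length(unique(o)) < 2) return(unique(g / o)[1])  # degenerate single level
    stats::coef(stats::lm(g ~ o))[["o"]]
  }
  slopes <- rows |>
    dplyr::group_by(.data$combination, .data$sco_source, .data$kc_source) |>
    dplyr::summarise(
      slope_pM_per_uM = if (dplyr::n() >= 2 && length(unique(.data$o_uM)) >= 2)
        ols_slope(.data$o_uM, .data$gamma_uM) * 1e6
      else .data$slope_term[1] * 1e6,
      analytic_slope_pM_per_uM = .data$slope_term[1] * 1e6,
      intercept_uM = .data$intercept_term[1],
      .groups = "drop"
    )

  gamma_range <- rows |>
    dplyr::group_by(.data$o_uM) |>
    dplyr::summarise(gamma_min = min(.data$gamma_uM),
                     gamma_max = max(.data$gamma_uM), .groups = "drop")

  structure(
    list(
      rows = rows,
      slopes = slopes,
      slope_min = min(slopes$slope_pM_per_uM),
      slope_max = max(slopes$slope_pM_per_uM),
      gamma_range = gamma_range,
      temperature_c = temperature_c,
      rl_ratio = rl_ratio,
      o_levels = o_levels,
      mode = mode
    ),
    class = "gamma_grid"
  )
}

#' @export
print.gamma_grid <- function(x, ...) {
  cat(sprintf(
    "Compensation-point grid: %d combinations x %d O2 levels at %g degC (r = %g)\n",
    nrow(x$slopes), length(x$o_levels), x$temperature_c, x$rl_ratio))
  cat(sprintf("Oxygen-response slope range: %.0f - %.0f pM CO2 / uM O2\n",
              x$slope_min, x$slope_max))
  print(x$slopes, ...)
  invisible(x)
}

#' Compensation point under hypothetical best-case kinetics
#'
#' Evaluates [gamma_co2()] with a specificity equal to `sco_multiplier` times
#' the highest temperature-adjusted specificity in `kinetics` and a Kc equal to
#' `kc_multiplier` times the lowest temperature-adjusted Kc (extrema taken
#' *after* Q10 adjustment), with the shared temperature-adjusted Ko. With the
#' default doubling/halving this asks what compensation point an organism's gas
#' exchange would need even if its rubisco were twice as selective and twice as
#' CO2-affine as any measured relative.
#'
#' @inheritParams gamma_grid
#' @param sco_multiplier Multiplier on the maximum adjusted specificity.
#'   Default 2.
#' @param kc_multiplier Multiplier on the minimum adjusted Kc. Default 0.5.
#' @param o_uM Dissolved O2, uM. Default: canonical 21% value at
#'   `temperature_c`.
#' @return A one-row tibble as from [gamma_co2()], plus the hypothetical
#'   parameter values used.
#' @export
#' @examples
#' hypothetical_gamma()  # ~1.3 uM at 40 degC, 21% O2
hypothetical_gamma <- function(kinetics = rubisco_cyanidiales(),
                               temperature_c = 40, sco_multiplier = 2,
                               kc_multiplier = 0.5, rl_ratio = NULL,
                               o_uM = NULL, q10 = q10_set(),
                               mode = c("canonical", "physics")) {
  mode <- match.arg(mode)
  if (nrow(kinetics) == 0) abort("`kinetics` must have at least one row.")
  rl_ratio <- rl_ratio %||% rl_ratio_default(temperature_c)
  o_uM <- o_uM %||% dissolved_o2(21, temperature_c, mode = mode)
  adj <- adjust_kinetics(kinetics, temperature_c, q10)
  sco_h <- sco_multiplier * max(adj$Sc_o_T)
  kc_h <- kc_multiplier * min(adj$Kc_uM_T)
  ko_h <- adj$Ko_uM_T[1]
  res <- gamma_co2(sco_h, kc_h, ko_h, rl_ratio, o_uM)
  dplyr::mutate(res, Sc_o_T = sco_h, Kc_uM_T = kc_h, Ko_uM_T = ko_h,
                temperature_c = temperature_c, rl_ratio = rl_ratio)
}

#' Oxygen-response slope of the compensation point
#'
#' Ordinary least-squares slope of compensation point against dissolved O2,
#' reported in pM CO2 per uM O2 with its standard error.
#'
#' @param data Data frame of compensation points by O2 level.
#' @param o,gamma Columns holding dissolved O2 (uM) and the compensation point
#'   (uM); defaults `o_uM` and `gamma_uM`.
#' @return A one-row tibble: `slope_pM_per_uM`, `se_pM_per_uM`,
#'   `intercept_uM`, `n`.
#' @export
#' @examples
#' gamma_co2(112.5, 7.49, 589, 0.13, c(20, 209, 398)) |> oxygen_slope()
oxygen_slope <- function(data, o = o_uM, gamma = gamma_uM) {
  o <- dplyr::pull(data, {{ o }})
  g <- dplyr::pull(data, {{ gamma }})
  if (length(unique(o)) < 2) {
    abort("At least two distinct O2 levels are required to fit a slope.")
  }
  fit <- stats::lm(g ~ o)
  # exact lines trigger a harmless perfect-fit note from summary.lm
  sm <- suppressWarnings(summary(fit))$coefficients
  se <- if (length(o) > 2) sm["o", "Std. Error"] else 0
  tibble(
    slope_pM_per_uM = sm["o", "Estimate"] * 1e6,
    se_pM_per_uM = se * 1e6,
    intercept_uM = sm["(Intercept)", "Estimate"],
    n = length(o)
  )
}

#' Classify a measured value against a calculated range
#'
#' Interval comparison of a measured value (with half-width, e.g. 2 standard
#' errors) against a range calculated from rubisco kinetics: `below` when even
#' the upper end of the measurement falls short of the calculated minimum (the
#' signature of a carbon-concentrating mechanism suppressing oxygenation),
#' `above` when the lower end exceeds the calculated maximum, `within`
#' otherwise.
#'
#' @param measured Measured value.
#' @param halfwidth Half-width of the measurement's uncertainty interval
#'   (same units). Default 0.
#' @param range_min,range_max Calculated range bounds (`range_min <= range_max`).
#' @return A tibble with the inputs and a `verdict` factor
#'   (below/within/above). Vectorised.
#' @export
#' @examples
#' classify_measurement(5425, 1396, 7046, 11153)  # below
classify_measurement <- function(measured, halfwidth = 0, range_min, range_max) {
  if (any(range_min > range_max)) abort("`range_min` must be <= `range_max`.")
  if (any(halfwidth < 0)) abort("`halfwidth` must be >= 0.")
  verdict <- dplyr::case_when(
    measured + halfwidth < range_min ~ "below",
    measured - halfwidth > range_max ~ "above",
    TRUE ~ "within"
  )
  tibble(measured = measured, halfwidth = halfwidth,
         range_min = range_min, range_max = range_max,
         verdict = factor(verdict, levels = c("below", "within", "above")))
}
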