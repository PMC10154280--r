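#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(
    term = c("amax", "km"),
    estimate = c(x$amax, x$km),
    std.error = c(x$se_amax, x$se_km),
    conf.low = c(x$amax - x$ci_amax, x$km - x$ci_km),
    conf.high = c(x$amax + x$ci_amax, x$km + x$ci_km)
  )
}

#' @export
glance.mm_fit <- function(x, ...) {
  tibble(km = x$km, amax = x$amax, ci_km = x$ci_km, ci_amax = x$ci_amax,
         conf_level = x$conf_level, n_points_used = x$n_points_used,
         sigma = summary(x$fit)$sigma)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "Michaelis-Menten fit (%d points): Km = %.3g +/- %.2g, Amax = %.3g +/- %.2g (%.0f%% CI half-widths)\n",
    x$n_points_used, x$km, x$ci_km, x$amax, x$ci_amax, 100 * x$conf_level))
  invisible(x)
}

#' @export
tidy.comp_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = sm[, "Std. Error"])
}

#' @export
glance.comp_fit <- function(x, ...) {
  tibble(gamma = x$gamma, slope = x$slope, intercept = x$intercept,
         threshold = x$threshold, n_points_used = x$n_points_used)
}

#' @export
print.comp_fit <- function(x, ...) {
  cat(sprintf(
    "Compensation-point fit (%d points <= %g): gamma = %.4g, slope = %.4g\n",
    x$n_points_used, x$threshold, x$gamma, x$slope))
  invisible(x)
}

#' @export
tidy.kok_fit <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = sm[, "Std. Error"])
}

#' @export
glance.kok_fit <- function(x, ...) {
  tibble(rl = x$rl, slope = x$slope,
         window_low = x$window[1], window_high = x$window[2],
         n_points_used = x$n_points_used)
}

#' @export
print.kok_fit <- function(x, ...) {
  cat(sprintf(
    "Kok fit (%d points in [%g, %g]): R_L = %.4g, slope = %.4g\n",
    x$n_points_used, x$window[1], x$window[2], x$rl, x$slope))
  invisible(x)
}

#' @export
tidy.gamma_grid <- function(x, ...) x$slopes

#' @export
glance.gamma_grid <- function(x, ...) {
  tibble(slope_min_pM_per_uM = x$slope_min,
         slope_max_pM_per_uM = x$slope_max,
         n_combinations = nrow(x$slopes),
         n_o_levels = length(x$o_levels),
         temperature_c = x$temperature_c,
         rl_ratio = x$rl_ratio,
         mode = x$mode)
}

#' @export
tidy.oxygen_response <- function(x, ...) x$per_replicate

#' @export
glance.oxygen_response <- function(x, ...) {
  tibble(mean_slope_pM_per_uM = x$mean_slope_pM_per_uM,
         se_pM_per_uM = x$se_pM_per_uM,
         ci2_pM_per_uM = x$ci2_pM_per_uM,
         n_replicates = x$n_replicates)
}
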