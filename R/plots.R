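#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_vline labs
#' @export
ggplot2::autoplot

#' @export
autoplot.mm_fit <- function(object, n = 200, ...) {
  grid <- data.frame(x = seq(0, max(object$data$x), length.out = n))
  grid$y <- object$amax * grid$x / (object$km + grid$x)
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_point() +
    geom_line(data = grid) +
    geom_vline(xintercept = object$km, linetype = "dashed") +
    labs(x = "CO2 driver", y = "Net assimilation",
         title = sprintf("Michaelis-Menten fit: Km = %.3g, Amax = %.3g",
                         object$km, object$amax))
}

#' @export
autoplot.comp_fit <- function(object, ...) {
  df <- data.frame(x = object$fit$model$x, y = object$fit$model$y)
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    geom_hline(yintercept = 0, linetype = "dotted") +
    geom_vline(xintercept = object$gamma, linetype = "dashed") +
    labs(x = "CO2 driver", y = "Net assimilation",
         title = sprintf("Compensation point = %.3g", object$gamma))
}

#' @export
autoplot.gamma_grid <- function(object, ...) {
  ggplot(object$rows,
         aes(x = .data$o_uM, y = .data$gamma_uM,
             colour = .data$combination)) +
    geom_line() +
    geom_point() +
    labs(x = "Dissolved O2 (uM)", y = "Compensation point (uM CO2)",
         colour = "Sc/o x Kc source",
         title = sprintf("Kinetics-calculated oxygen response at %g degC",
                         object$temperature_c))
}

#' Plot dissolved inorganic carbon pools across pH
#'
#' Convenience wrapper around [speciate_from_pco2()]: pools (uM, log scale) as
#' a function of pH at fixed headspace pCO2 and temperature. CO2(aq) is flat
#' across pH under the fixed-pCO2 convention; bicarbonate and carbonate climb.
#'
#' @param pco2_ppm Headspace CO2, ppm. Default 400.
#' @param temperature_c Temperature, degC. Default 40.
#' @param ph_range pH limits. Default `c(1, 9)`.
#' @param formulation Constant set, see [carbonate_constants()].
#' @return A ggplot object.
#' @export
plot_speciation <- function(pco2_ppm = 400, temperature_c = 40,
                            ph_range = c(1, 9),
                            formulation = c("lueker", "plummer")) {
  formulation <- match.arg(formulation)
  ph <- seq(ph_range[1], ph_range[2], by = 0.05)
  long <- speciate_from_pco2(pco2_ppm, ph, temperature_c,
                             formulation = formulation) |>
    dplyr::select("ph", "co2_aq_uM", "hco3_uM", "co3_uM") |>
    tidyr::pivot_longer(-"ph", names_to = "pool", values_to = "uM")
  ggplot(long, aes(x = .data$ph, y = .data$uM, colour = .data$pool)) +
    geom_line() +
    ggplot2::scale_y_log10() +
    labs(x = "pH", y = "Concentration (uM)", colour = "Pool",
         title = sprintf("Dissolved Ci at %g ppm CO2, %g degC",
                         pco2_ppm, temperature_c))
}
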