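#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a calibrated half-life law against the per-temperature fits
#'
#' Fitted half-lives on a log scale versus temperature, with the
#' log-linear regression line whose slope is the exponential coefficient
#' `a`.
#'
#' @param object A `calibration_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calibration_result
#' @export
autoplot.calibration_result <- function(object, ...) {
  fits <- object$fits
  p <- object$params
  grid <- tibble::tibble(
    temperature_C = seq(min(fits$temperature_C), max(fits$temperature_C),
                        length.out = 100))
  grid$lambda <- half_life(grid$temperature_C, p)
  ggplot2::ggplot(fits, ggplot2::aes(x = .data$temperature_C)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$lambda),
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$lambda_hat)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Temperature (°C)", y = "Half-life λ (s)",
                  title = sprintf("Half-life law: a = %.3g /°C, T0 = %.1f °C",
                                  p$a, p$T0)) +
    ggplot2::theme_minimal()
}

#' Plot kinetic data with the fitted Weibull curves
#'
#' @param dataset Kinetic data (`temperature_C`, `time_s`, `fraction`).
#' @param result Optional `calibration_result` whose law is overlaid.
#' @return A ggplot, faceted by temperature.
#' @export
plot_kinetics <- function(dataset, result = NULL) {
  p <- ggplot2::ggplot(dataset,
                       ggplot2::aes(x = .data$time_s, y = .data$fraction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~temperature_C, scales = "free_x") +
    ggplot2::labs(x = "Exposure time (s)", y = "Surviving fraction") +
    ggplot2::theme_minimal()
  if (!is.null(result)) {
    curves <- dataset |>
      dplyr::distinct(.data$temperature_C) |>
      dplyr::rowwise() |>
      dplyr::reframe(
        time_s = seq(0, max(dataset$time_s[dataset$temperature_C ==
                                             .data$temperature_C]),
                     length.out = 100),
        temperature_C = .data$temperature_C) |>
      dplyr::mutate(fraction = weibull_survival(.data$time_s,
                                                .data$temperature_C,
                                                result$params))
    p <- p + ggplot2::geom_line(data = curves, colour = "firebrick")
  }
  p
}

#' Plot a rapid-light-curve fit
#'
#' Measured rETR per light step with the fitted Eilers-Peeters curve.
#'
#' @param object An `ep_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ep_fit
#' @export
autoplot.ep_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    irradiance = seq(0, max(d$irradiance), length.out = 200))
  grid$retr <- eilers_peeters(grid$irradiance, object$alpha, object$P_max,
                              object$I_opt)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$irradiance, y = .data$retr)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Irradiance (µmol m⁻² s⁻¹)",
                  y = "rETR",
                  title = sprintf("α = %.3g, P_max = %.3g, I_opt = %.3g",
                                  object$alpha, object$P_max, object$I_opt)) +
    ggplot2::theme_minimal()
}

#' Plot a year of simulated culture state
#'
#' Daily end-of-day viable and active fractions, with collapse days
#' marked.
#'
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sim_result
#' @export
autoplot.sim_result <- function(object, ...) {
  d <- object$daily |>
    tidyr::pivot_longer(cols = c("f_V", "f_A"), names_to = "endpoint",
                        values_to = "fraction")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$fraction,
                                  colour = .data$endpoint)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$daily$day[object$daily$collapse],
                        linetype = "dotted", colour = "grey60") +
    ggplot2::scale_colour_manual(
      values = c(f_V = "#1b9e77", f_A = "#d95f02"),
      labels = c(f_V = "viable", f_A = "active")) +
    ggplot2::labs(x = "Day", y = "End-of-day fraction", colour = NULL) +
    ggplot2::theme_minimal()
}
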