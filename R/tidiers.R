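#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a per-temperature Weibull fit
#'
#' @param x A `weibull_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy weibull_fit
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble::tibble(term = c("lambda", "n"),
                 estimate = c(x$lambda_hat, x$n_hat),
                 std.error = c(x$se_lambda, x$se_n))
}

#' @rdname tidy.weibull_fit
#' @method glance weibull_fit
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble::tibble(temperature_C = x$temperature, rss = x$rss,
                 n_obs = x$n_obs, converged = x$converged)
}

#' Tidy a calibration result
#'
#' @param x A `calibration_result`.
#' @param ... Unused.
#' @return One row per parameter (`a`, `T0`, `n`) with estimates and,
#'   when computed, Monte-Carlo 95% interval bounds.
#' @method tidy calibration_result
#' @export
tidy.calibration_result <- function(x, ...) {
  out <- tibble::tibble(term = c("a", "T0", "n"),
                        estimate = c(x$params$a, x$params$T0, x$params$n))
  if (!is.null(x$ci)) {
    out$conf.low <- x$ci$lower[match(out$term, x$ci$parameter)]
    out$conf.high <- x$ci$upper[match(out$term, x$ci$parameter)]
  }
  out
}

#' @rdname tidy.calibration_result
#' @method glance calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(endpoint = x$params$endpoint,
                 r_squared = x$regression$r_squared,
                 n_temperatures = nrow(x$fits),
                 n_excluded = length(x$excluded),
                 mc_iter = if (is.null(x$mc)) 0L else x$mc$n_iter)
}

#' Tidy an Eilers-Peeters light-curve fit
#'
#' @param x An `ep_fit`.
#' @param ... Unused.
#' @return One row per parameter (`alpha`, `P_max`, `I_opt`).
#' @method tidy ep_fit
#' @export
tidy.ep_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "P_max", "I_opt"),
                 estimate = c(x$alpha, x$P_max, x$I_opt))
}

#' @rdname tidy.ep_fit
#' @method glance ep_fit
#' @export
glance.ep_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, P_max = x$P_max, I_opt = x$I_opt,
                 rss = x$rss, n_steps = x$n_steps,
                 converged = x$converged, extrapolated = x$extrapolated)
}

#' Summarise a simulation result
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return The one-row summary tibble (collapse/deactivation day counts,
#'   days over the lethal threshold, light-loss fraction).
#' @method glance sim_result
#' @export
glance.sim_result <- function(x, ...) {
  x$summary
}
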