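#' Thermal-dose Weibull parameter set
#'
#' Bundles the three parameters of the exponential half-life law and Weibull
#' survival model for one endpoint (viability or photosynthetic activity):
#' the half-life of a culture at temperature `T` is
#' \eqn{\lambda(T) = \exp(a (T - T_0))} seconds, and survival after an
#' exposure of duration `t` is \eqn{\exp(-(t/\lambda(T))^n)}.
#'
#' @param a Exponential coefficient of the half-life law, per degree C.
#'   Negative for organisms whose half-life shrinks with temperature.
#' @param T0 Reference temperature, degrees C: the temperature at which the
#'   half-life equals one second.
#' @param n Weibull shape factor (dimensionless, > 0). Values well above 1
#'   produce a shoulder before rapid decay.
#' @param endpoint `"viability"` or `"activity"`; a label carried through
#'   calibration and simulation output.
#'
#' @return An object of class `survival_params` (a named list).
#' @examples
#' p <- survival_params(-0.218, 81.5, 4.84)
#' half_life(45, p)
#' @export
survival_params <- function(a, T0, n, endpoint = c("viability", "activity")) {
  endpoint <- match.arg(endpoint)
  stopifnot(is.numeric(a), is.numeric(T0), is.numeric(n),
            length(a) == 1L, length(T0) == 1L, length(n) == 1L)
  if (!is.finite(n) || n <= 0) {
    rlang::abort("`n` must be a finite positive shape factor.",
                 class = "thermodose_domain_error")
  }
  if (!is.finite(a) || !is.finite(T0)) {
    rlang::abort("`a` and `T0` must be finite.",
                 class = "thermodose_domain_error")
  }
  structure(list(a = a, T0 = T0, n = n, endpoint = endpoint),
            class = "survival_params")
}

#' @export
print.survival_params <- function(x, ...) {
  cat(sprintf(
    "<survival_params> endpoint = %s\n  a  = %.4g 1/degC\n  T0 = %.4g degC\n  n  = %.4g\n",
    x$endpoint, x$a, x$T0, x$n))
  invisible(x)
}

#' Calibrated Weibull parameter presets for Dunaliella salina
#'
#' Published point estimates of the thermal-dose law for *D. salina*
#' viability (erythrosine exclusion staining or FDA enzymatic staining,
#' measured 1 h after heat exposure) and for photosynthetic activity (PAM
#' initial slope). Useful as generator truth and simulator defaults.
#'
#' @return A `survival_params` object.
#' @name params_presets
NULL

#' @rdname params_presets
#' @export
params_erythrosine <- function() survival_params(-0.218, 81.5, 4.84, "viability")

#' @rdname params_presets
#' @export
params_fda <- function() survival_params(-0.232, 80.1, 5.59, "viability")

#' @rdname params_presets
#' @export
params_activity <- function() survival_params(-0.132, 92.2, 3.97, "activity")

as_survival_params <- function(x) {
  if (inherits(x, "survival_params")) return(x)
  if (is.list(x) && all(c("a", "T0", "n") %in% names(x))) {
    return(survival_params(x$a, x$T0, x$n,
                           endpoint = x$endpoint %||% "viability"))
  }
  rlang::abort("Cannot interpret `params`: need a `survival_params` or a list with a, T0, n.",
               class = "thermodose_domain_error")
}

check_nonneg_time <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) {
    rlang::abort("Exposure times must be finite and >= 0.",
                 class = "thermodose_domain_error")
  }
}

#' Half-life of a culture at a constant temperature
#'
#' The exposure time that reduces the population to exp(-1) (about 37%) of
#' its initial value: \eqn{\lambda(T) = \exp(a (T - T_0))}.
#'
#' @param temp_C Temperature(s), degrees C.
#' @param params A [survival_params()] object.
#' @return Half-life in seconds, vectorised over `temp_C`.
#' @examples
#' half_life(45, params_erythrosine())
#' @export
half_life <- function(temp_C, params) {
  params <- as_survival_params(params)
  if (any(!is.finite(temp_C))) {
    rlang::abort("`temp_C` must be finite.", class = "thermodose_domain_error")
  }
  exp(params$a * (temp_C - params$T0))
}

#' Weibull survival under constant temperature
#'
#' Surviving fraction after `t` seconds at `temp_C`:
#' \eqn{\exp(-(t/\lambda(T))^n)}.
#'
#' @param t Exposure time(s), seconds (>= 0).
#' @inheritParams half_life
#' @return Fraction in \[0, 1\], vectorised.
#' @examples
#' weibull_survival(3600, 45, params_erythrosine())
#' @export
weibull_survival <- function(t, temp_C, params) {
  params <- as_survival_params(params)
  check_nonneg_time(t)
  survival_from_dose(t / half_life(temp_C, params), params$n)
}

#' Thermal dose of a constant-temperature exposure
#'
#' Dimensionless dose `t / lambda(T)`, i.e. exposure time scaled by the
#' half-life at that temperature. A dose of 1 kills 63% of the population.
#'
#' @inheritParams weibull_survival
#' @return Dimensionless dose, vectorised.
#' @export
thermal_dose_constant <- function(t, temp_C, params) {
  params <- as_survival_params(params)
  check_nonneg_time(t)
  t * exp(-params$a * (temp_C - params$T0))
}

validate_temperature_series <- function(series) {
  if (!is.data.frame(series) || !all(c("time_s", "temp_C") %in% names(series))) {
    rlang::abort("A temperature series needs columns `time_s` and `temp_C`.",
                 class = "thermodose_domain_error")
  }
  if (nrow(series) < 2L) {
    rlang::abort("A temperature series needs at least two samples.",
                 class = "thermodose_domain_error")
  }
  if (any(!is.finite(series$time_s)) || any(diff(series$time_s) <= 0)) {
    rlang::abort("`time_s` must be finite and strictly increasing.",
                 class = "thermodose_domain_error")
  }
  if (any(!is.finite(series$temp_C))) {
    rlang::abort("`temp_C` must be finite.", class = "thermodose_domain_error")
  }
  invisible(series)
}

# Insert linearly interpolated threshold-crossing knots so that the
# trapezoidal rule sees the exact on/off boundary of the integrand.
insert_threshold_crossings <- function(time_s, temp_C, threshold) {
  above <- temp_C >= threshold
  cross <- which(above[-length(above)] != above[-1L])
  if (length(cross) == 0L) return(list(time_s = time_s, temp_C = temp_C))
  t_new <- time_s[cross] + (threshold - temp_C[cross]) *
    (time_s[cross + 1L] - time_s[cross]) / (temp_C[cross + 1L] - temp_C[cross])
  time_all <- c(time_s, t_new)
  temp_all <- c(temp_C, rep(threshold, length(t_new)))
  ord <- order(time_all)
  list(time_s = time_all[ord], temp_C = temp_all[ord])
}

#' Thermal dose accumulated over a temperature time series
#'
#' Trapezoidal integral of \eqn{\exp(-a (T(t) - T_0))} over time, with the
#' temperature linearly interpolated between samples. When `threshold` is
#' given, the integrand is zero wherever `T < threshold` and the crossing
#' times are located by linear interpolation, so dose only accumulates
#' during supra-threshold (mortality-event) periods.
#'
#' @param series Data frame with columns `time_s` (strictly increasing,
#'   seconds) and `temp_C`.
#' @param params A [survival_params()] object.
#' @param threshold Optional lethal temperature, degrees C.
#' @return A single dimensionless dose.
#' @examples
#' s <- data.frame(time_s = c(0, 3600), temp_C = c(45, 45))
#' thermal_dose_series(s, params_erythrosine())
#' @export
thermal_dose_series <- function(series, params, threshold = NULL) {
  params <- as_survival_params(params)
  validate_temperature_series(series)
  tt <- series$time_s
  TT <- series$temp_C
  if (!is.null(threshold)) {
    k <- insert_threshold_crossings(tt, TT, threshold)
    tt <- k$time_s
    TT <- k$temp_C
  }
  f <- exp(-params$a * (TT - params$T0))
  seg <- 0.5 * (f[-1L] + f[-length(f)]) * diff(tt)
  if (!is.null(threshold)) {
    # crossing knots are inserted above, so no segment straddles the
    # threshold; count only segments lying entirely at or above it (the
    # integrand is zero below, including the sub-threshold side of a
    # crossing knot)
    above <- TT >= threshold
    seg[!(above[-1L] & above[-length(above)])] <- 0
  }
  sum(seg)
}

#' Survival from an accumulated thermal dose
#'
#' \eqn{\exp(-d^n)}: the Weibull survival written in terms of the
#' dimensionless dose, valid for arbitrary temperature histories.
#'
#' @param dose Dimensionless thermal dose(s) (>= 0).
#' @param n Weibull shape factor (> 0), or a [survival_params()] object
#'   whose `n` is used.
#' @return Fraction(s) in \[0, 1\].
#' @export
survival_from_dose <- function(dose, n) {
  if (inherits(n, "survival_params")) n <- n$n
  if (any(!is.finite(dose)) || any(dose < 0)) {
    rlang::abort("`dose` must be finite and >= 0.",
                 class = "thermodose_domain_error")
  }
  pmin(1, pmax(0, exp(-dose^n)))
}

#' First-order (log-linear) survival
#'
#' Constant-mortality-rate reference model: \eqn{\exp(-m t)}.
#'
#' @param t Exposure time(s), seconds (>= 0).
#' @param m Mortality rate, per second (>= 0).
#' @return Fraction(s) in \[0, 1\].
#' @export
first_order_survival <- function(t, m) {
  check_nonneg_time(t)
  if (!is.finite(m) || m < 0) {
    rlang::abort("`m` must be finite and >= 0.",
                 class = "thermodose_domain_error")
  }
  pmin(1, pmax(0, exp(-m * t)))
}

#' Geeraerd shoulder/tail survival curve
#'
#' Integrates the two-equation shoulder model
#' \deqn{dN/dt = -m_m N \frac{1}{1 + C_c}\left(1 - \frac{N_{res}}{N}\right),
#'       \quad dC_c/dt = -m_m C_c}
#' with an adaptive stiff-capable solver. `C_c` is a physiological-state
#' variable whose decay sets the shoulder duration (about
#' \eqn{\ln(C_{c0})/m_m} for large `Cc0`); `N_res` is a residual
#' (stress-resistant) subpopulation.
#'
#' @param t_grid Output times, seconds, increasing from 0.
#' @param m_m Maximal decay rate, per second (>= 0).
#' @param Cc0 Initial physiological state (>= 0); large values give a
#'   pronounced shoulder.
#' @param N_res Residual population (same units as `N0`, < `N0`).
#' @param N0 Initial population.
#' @param rtol,atol Solver tolerances.
#' @return A tibble with columns `time_s` and `N`.
#' @export
geeraerd_survival <- function(t_grid, m_m, Cc0, N_res = 0, N0 = 1,
                              rtol = 1e-8, atol = 1e-12) {
  stopifnot(m_m >= 0, Cc0 >= 0, N_res >= 0, N_res <= N0)
  if (length(t_grid) < 2L || t_grid[1L] != 0 || any(diff(t_grid) <= 0)) {
    rlang::abort("`t_grid` must increase strictly from 0.",
                 class = "thermodose_domain_error")
  }
  rhs <- function(t, y, p) {
    N <- y[1L]; Cc <- y[2L]
    dN <- -p$m_m * N * (1 / (1 + Cc)) * (1 - p$N_res / N)
    list(c(dN, -p$m_m * Cc))
  }
  sol <- deSolve::lsoda(
    y = c(N = N0, Cc = Cc0), times = t_grid, func = rhs,
    parms = list(m_m = m_m, N_res = N_res),
    rtol = rtol, atol = atol)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1L] < 0) {
    rlang::abort("ODE integration of the Geeraerd model failed.",
                 class = "thermodose_integration_error")
  }
  tibble::tibble(time_s = sol[, "time"], N = pmax(N_res, sol[, "N"]))
}

#' Log-logistic survival curve
#'
#' Sigmoid-in-log-time model
#' \deqn{N(t) = N_0 \exp\left(\alpha + \frac{\omega - \alpha}
#'   {1 + \exp\left(4\sigma(\tau - \log t)/(\omega - \alpha)\right)}\right)}
#' with plateaus at \eqn{N_0 e^\alpha} (short exposures) and
#' \eqn{N_0 e^\omega} (long exposures). The log of time is base-10 by
#' default (the convention of the log-logistic inactivation literature);
#' set `log_base` to use another base.
#'
#' @param t Exposure time(s), seconds (> 0; the log of `t` is taken).
#' @param alpha_ll,omega_ll Log viable counts at the start and end plateaus.
#' @param sigma_ll Shape factor (maximum slope in log time).
#' @param tau_ll Scale factor: log-time of the inflection.
#' @param N0 Initial count (default 1 for fractions).
#' @param log_base Base of the time logarithm (default 10).
#' @return Count(s) (or fraction(s) when `N0 = 1`).
#' @export
log_logistic_survival <- function(t, alpha_ll, omega_ll, sigma_ll, tau_ll,
                                  N0 = 1, log_base = 10) {
  if (any(!is.finite(t)) || any(t <= 0)) {
    rlang::abort("`t` must be finite and > 0 (its log is taken).",
                 class = "thermodose_domain_error")
  }
  lt <- log(t, base = log_base)
  N0 * exp(alpha_ll + (omega_ll - alpha_ll) /
             (1 + exp(4 * sigma_ll * (tau_ll - lt) / (omega_ll - alpha_ll))))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
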