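#' Configuration for the full-scale collapse simulator
#'
#' @param T_lethal Lethal temperature threshold, degrees C. Thermal dose
#'   accumulates only while the culture is at or above it (default 43,
#'   below which no viability loss is observed for *D. salina*).
#' @param collapse_threshold End-of-day viability below this marks a
#'   culture collapse (default 0.01, i.e. 1%).
#' @param policy Re-inoculation policy: `"next-sunrise"` restarts the
#'   culture at sunrise the day after a collapse; `"delay-days"` leaves
#'   the reactor dead for `delay_days` days first (growing an inoculum
#'   takes time at scale).
#' @param delay_days Days between a collapse and re-inoculation under the
#'   `"delay-days"` policy (default 5).
#' @param viability_params,activity_params [survival_params()] for the
#'   two endpoints (defaults: the erythrosine viability and PAM activity
#'   presets).
#' @param inoculum Biomass concentration restored at re-inoculation,
#'   cells m^-3.
#' @return A `sim_config` list.
#' @export
sim_config <- function(T_lethal = 43, collapse_threshold = 0.01,
                       policy = c("next-sunrise", "delay-days"),
                       delay_days = 5,
                       viability_params = params_erythrosine(),
                       activity_params = params_activity(),
                       inoculum = 1e11) {
  policy <- match.arg(policy)
  stopifnot(collapse_threshold > 0, collapse_threshold < 1, delay_days >= 0)
  structure(list(T_lethal = T_lethal,
                 collapse_threshold = collapse_threshold,
                 policy = policy,
                 delay_days = if (policy == "next-sunrise") 0 else delay_days,
                 viability_params = as_survival_params(viability_params),
                 activity_params = as_survival_params(activity_params),
                 inoculum = inoculum),
            class = "sim_config")
}

#' Growth model plug-in
#'
#' Between mortality events biomass follows
#' \eqn{dN/dt = \Phi(T)\,\mu\,N}. The default temperature response is
#' flat (`Phi = 1`); a cardinal-temperature response can be plugged in as
#' any vectorised function of temperature.
#'
#' @param mu Specific growth rate, per second (default one doubling per
#'   day).
#' @param phi Vectorised temperature-response function `Phi(T) >= 0`.
#' @return A `growth_model` list.
#' @export
growth_model <- function(mu = log(2) / 86400, phi = function(temp_C) rep(1, length(temp_C))) {
  stopifnot(mu >= 0, is.function(phi))
  structure(list(mu = mu, phi = phi), class = "growth_model")
}

#' Culture state
#'
#' @param f_V,f_A Viable and active fractions in \[0, 1\].
#' @param biomass Cell concentration, cells m^-3.
#' @param status `"growing"`, `"dead"` or `"awaiting-reinoculation"`.
#' @return A `culture_state` list.
#' @export
culture_state <- function(f_V = 1, f_A = 1, biomass = 1e11,
                          status = "growing") {
  stopifnot(f_V >= 0, f_V <= 1, f_A >= 0, f_A <= 1, biomass >= 0,
            status %in% c("growing", "dead", "awaiting-reinoculation"))
  structure(list(f_V = f_V, f_A = f_A, biomass = biomass, status = status),
            class = "culture_state")
}

#' Detect mortality events in a temperature series
#'
#' A mortality event is a maximal contiguous period with temperature at
#' or above the lethal threshold. Crossing times are located by linear
#' interpolation between samples, and the viability and activity thermal
#' doses are integrated over each event.
#'
#' @param series Temperature series (`time_s`, `temp_C`).
#' @param T_lethal Lethal threshold, degrees C.
#' @param viability_params,activity_params [survival_params()] used for
#'   the per-event dose integrals.
#' @return A tibble with one row per event: `t_s`, `t_e` (seconds),
#'   `dose_V`, `dose_A`. Zero rows when the series never reaches the
#'   threshold.
#' @export
detect_mortality_events <- function(series, T_lethal = 43,
                                    viability_params = params_erythrosine(),
                                    activity_params = params_activity()) {
  validate_temperature_series(series)
  k <- insert_threshold_crossings(series$time_s, series$temp_C, T_lethal)
  above <- k$temp_C >= T_lethal
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in which(r$values)) {
    i0 <- starts[i]; i1 <- ends[i]
    # extend to the bracketing threshold knots if present
    if (i0 > 1L && k$temp_C[i0 - 1L] == T_lethal) i0 <- i0 - 1L
    if (i1 < length(above) && k$temp_C[i1 + 1L] == T_lethal) i1 <- i1 + 1L
    t_s <- k$time_s[i0]; t_e <- k$time_s[i1]
    if (t_e <= t_s) next
    sub <- data.frame(time_s = k$time_s[i0:i1], temp_C = k$temp_C[i0:i1])
    out[[length(out) + 1L]] <- tibble::tibble(
      t_s = t_s, t_e = t_e,
      dose_V = thermal_dose_series(sub, viability_params, threshold = T_lethal),
      dose_A = thermal_dose_series(sub, activity_params, threshold = T_lethal))
  }
  if (length(out) == 0L) {
    return(tibble::tibble(t_s = numeric(), t_e = numeric(),
                          dose_V = numeric(), dose_A = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Apply a mortality event to a culture state
#'
#' Multiplies the viable and active fractions by the Weibull survival of
#' the event doses: \eqn{f_V \leftarrow f_V e^{-d_V^{n_V}}},
#' \eqn{f_A \leftarrow f_A e^{-d_A^{n_A}}}. Fractions never increase:
#' de-activated and dead cells do not recover.
#'
#' @param state A [culture_state()].
#' @param event One row of [detect_mortality_events()] output (or any
#'   list with `dose_V`, `dose_A`).
#' @param config A [sim_config()] supplying the endpoint shape factors.
#' @return The updated `culture_state`.
#' @export
apply_event <- function(state, event, config) {
  stopifnot(inherits(state, "culture_state"), inherits(config, "sim_config"))
  state$f_V <- state$f_V * survival_from_dose(event$dose_V,
                                              config$viability_params$n)
  state$f_A <- state$f_A * survival_from_dose(event$dose_A,
                                              config$activity_params$n)
  state
}

#' Grow a culture over a sub-lethal interval
#'
#' Exact exponential update for piecewise-constant rates:
#' \eqn{N \leftarrow N e^{\Phi(T)\mu\,dt}}. Fractions are unchanged.
#'
#' @param state A [culture_state()].
#' @param dt Interval length, seconds.
#' @param temp_C Temperature during the interval, degrees C.
#' @param model A [growth_model()].
#' @return The updated `culture_state`.
#' @export
grow <- function(state, dt, temp_C, model) {
  stopifnot(inherits(state, "culture_state"), inherits(model, "growth_model"),
            dt >= 0)
  if (state$status == "growing") {
    state$biomass <- state$biomass * exp(model$phi(temp_C) * model$mu * dt)
  }
  state
}

resolve_climate <- function(temps, irradiance = NULL) {
  if (is.null(irradiance)) {
    if (!all(c("time_s", "temp_C", "irradiance") %in% names(temps))) {
      rlang::abort("Climate needs columns `time_s`, `temp_C`, `irradiance` (or pass two aligned series).",
                   class = "thermodose_domain_error")
    }
    return(tibble::as_tibble(temps))
  }
  if (!identical(temps$time_s, irradiance$time_s)) {
    rlang::abort("Temperature and irradiance series are misaligned: their time grids differ.",
                 class = "thermodose_domain_error")
  }
  tibble::tibble(time_s = temps$time_s, temp_C = temps$temp_C,
                 irradiance = irradiance$irradiance)
}

trapz <- function(x, y) sum(0.5 * (y[-1L] + y[-length(y)]) * diff(x))

#' Run the full-scale culture-collapse simulation
#'
#' Day-by-day loop over an aligned temperature/irradiance record: supra-
#' lethal periods accumulate viability and activity thermal dose (doses
#' of same-day events merge additively before the shape-factor power is
#' applied), biomass grows below the lethal threshold, and at local
#' midnight the end-of-day viability is checked against the collapse
#' threshold. After a collapse the culture stays dead until re-inoculation
#' (at sunrise the next day, or after the configured delay), and the
#' incident light of the collapse day and of every awaiting day is booked
#' as lost - under the light-proportional productivity assumption that
#' light is absorbed by dead cells and wasted.
#'
#' @param temps Either a full climate table (`time_s`, `temp_C`,
#'   `irradiance`) or a temperature series to be paired with
#'   `irradiance`.
#' @param irradiance Optional irradiance series (`time_s`, `irradiance`)
#'   on the same time grid.
#' @param config A [sim_config()].
#' @param growth A [growth_model()].
#' @return A `sim_result`: `$daily` tibble (per-day doses, end-of-day
#'   fractions, biomass, flags, light) and `$summary` one-row tibble
#'   (`collapse_days`, `deactivation_days`, `days_over_lethal`,
#'   `light_loss_fraction`, `n_days`).
#' @examples
#' clim <- gen_climate(gen_config(seed = 1, heatwave_days = c(150, 200)))
#' run_simulation(clim, config = sim_config())
#' @export
run_simulation <- function(temps, irradiance = NULL, config = sim_config(),
                           growth = growth_model()) {
  stopifnot(inherits(config, "sim_config"), inherits(growth, "growth_model"))
  climate <- resolve_climate(temps, irradiance)
  validate_temperature_series(climate)
  if (max(climate$time_s) - min(climate$time_s) < 86400) {
    rlang::abort("Climate record must span at least one day.",
                 class = "thermodose_domain_error")
  }

  # a sample falling exactly on the final midnight closes the previous day
  days <- seq(floor(min(climate$time_s) / 86400),
              floor((max(climate$time_s) - 1e-6) / 86400))
  state <- culture_state(biomass = config$inoculum)
  reinoculate_on <- -Inf   # day index at whose start the culture restarts
  nV <- config$viability_params$n
  nA <- config$activity_params$n

  rows <- vector("list", length(days))
  for (j in seq_along(days)) {
    d <- days[j]
    idx <- which(climate$time_s >= d * 86400 & climate$time_s <= (d + 1) * 86400)
    sub <- climate[idx, , drop = FALSE]
    awaiting_at_start <- state$status != "growing"
    if (awaiting_at_start && d >= reinoculate_on) {
      state <- culture_state(biomass = config$inoculum)  # sunrise re-inoculation
      awaiting_at_start <- FALSE
    }

    day_light <- if (nrow(sub) >= 2L) trapz(sub$time_s, sub$irradiance) else 0
    max_T <- max(sub$temp_C)
    dose_V <- dose_A <- 0
    if (nrow(sub) >= 2L && is.finite(config$T_lethal) &&
        max_T >= config$T_lethal) {
      dose_V <- thermal_dose_series(sub[, c("time_s", "temp_C")],
                                    config$viability_params,
                                    threshold = config$T_lethal)
      dose_A <- thermal_dose_series(sub[, c("time_s", "temp_C")],
                                    config$activity_params,
                                    threshold = config$T_lethal)
    }

    collapse <- deactivation <- FALSE
    if (state$status == "growing") {
      if (dose_V > 0 || dose_A > 0) {
        state <- apply_event(state, list(dose_V = dose_V, dose_A = dose_A),
                             config)
      }
      # growth only over sub-lethal stretches of the day
      if (nrow(sub) >= 2L && growth$mu > 0) {
        below <- sub$temp_C < config$T_lethal
        dt <- diff(sub$time_s)
        seg_ok <- below[-length(below)] & below[-1L]
        Tmid <- 0.5 * (sub$temp_C[-length(below)] + sub$temp_C[-1L])
        gexp <- sum(growth$phi(Tmid[seg_ok]) * growth$mu * dt[seg_ok])
        state$biomass <- state$biomass * exp(gexp)
      }
      # local-midnight check
      collapse <- state$f_V < config$collapse_threshold
      deactivation <- state$f_A < config$collapse_threshold
      if (collapse) {
        state$status <- "awaiting-reinoculation"
        reinoculate_on <- d + 1 + config$delay_days
      }
    }

    lost <- collapse || awaiting_at_start || state$status != "growing"
    rows[[j]] <- tibble::tibble(
      day = d, max_temp_C = max_T, dose_V = dose_V, dose_A = dose_A,
      f_V = state$f_V, f_A = state$f_A, biomass = state$biomass,
      status = state$status,
      over_lethal = max_T >= config$T_lethal,
      collapse = collapse, deactivation = deactivation,
      light = day_light, lost_light = lost)
  }

  daily <- dplyr::bind_rows(rows)
  total_light <- sum(daily$light)
  summary <- tibble::tibble(
    collapse_days = sum(daily$collapse),
    deactivation_days = sum(daily$deactivation),
    days_over_lethal = sum(daily$over_lethal),
    light_loss_fraction = if (total_light > 0)
      sum(daily$light[daily$lost_light]) / total_light else 0,
    n_days = nrow(daily))
  structure(list(daily = daily, summary = summary, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<sim_result> %d days: %d collapses, %d deactivation days, ",
                     "%d days over %.3g degC, light loss %.1f%%\n"),
              s$n_days, s$collapse_days, s$deactivation_days,
              s$days_over_lethal, x$config$T_lethal,
              100 * s$light_loss_fraction))
  invisible(x)
}

#' Fractional productivity loss from a simulation
#'
#' Under the assumption that biofuel productivity is proportional to the
#' light captured by live cells, the fraction of annual incident light
#' arriving while the culture is dead or awaiting re-inoculation is the
#' fractional annual productivity loss.
#'
#' @param result A `sim_result`.
#' @return A fraction in \[0, 1\].
#' @export
productivity_loss <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  result$summary$light_loss_fraction
}
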