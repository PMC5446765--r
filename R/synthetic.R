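#' Configuration for the synthetic-data generators
#'
#' One seeded configuration object drives every generator. Defaults
#' reproduce the study conditions the pipeline was designed for: six
#' water-bath temperatures between 41 and 60 degC with duplicate
#' measurements and roughly 3% measurement noise on the fraction scale,
#' the 7-step rapid-light-curve irradiance ladder, bimodal three-channel
#' cytometry, and an hourly diel/seasonal climate with optional injected
#' heatwave days.
#'
#' @param seed Integer seed; every generator is bit-reproducible given
#'   the seed and config.
#' @param params Generating [survival_params()] (truth of the kinetics).
#' @param temperatures Water-bath temperatures, degrees C.
#' @param n_times Exposure times per temperature (>= 6 in the emulated
#'   protocol).
#' @param duplicates Replicates per (temperature, time) point.
#' @param noise_sd Gaussian measurement noise sd on the fraction scale.
#' @param endpoint,marker,assay_delay_h Metadata labels attached to
#'   kinetic records.
#' @param T_lethal Temperatures below this generate flat (no-loss)
#'   curves, as observed at 41-42 degC.
#' @param rlc_alpha,rlc_P_max,rlc_I_opt Eilers-Peeters truth of generated
#'   light curves.
#' @param rlc_noise Multiplicative noise sd on the fluorescence signal.
#' @param rlc_ladder Actinic irradiance steps, umol m^-2 s^-1.
#' @param rlc_FM Maximum fluorescence level, arbitrary units.
#' @param cyto_background Non-algal event fraction in cytometry tables.
#' @param cyto_sdlog Log-scale spread of each fluorescence mode.
#' @param climate_mean,climate_seasonal,climate_diel Annual mean, seasonal
#'   amplitude and diel amplitude of the synthetic temperature series,
#'   degrees C.
#' @param heatwave_days Integer day indices (0-based) on which a
#'   supra-lethal spike is injected.
#' @param heatwave_temp,heatwave_hours Plateau temperature (degC) and
#'   duration (h) of injected spikes, centred on early afternoon.
#' @param year_days Length of the generated climate record, days.
#' @param sample_step_s Climate sampling step, seconds (default hourly).
#' @param irradiance_peak Clear-sky midday irradiance, umol m^-2 s^-1.
#' @param irradiance_seasonal Relative seasonal modulation of the daily
#'   irradiance peak (0 turns modulation off).
#' @return A `gen_config` list.
#' @export
gen_config <- function(seed = 1L,
                       params = params_erythrosine(),
                       temperatures = c(41, 42, 43, 45, 50, 60),
                       n_times = 8L,
                       duplicates = 2L,
                       noise_sd = 0.03,
                       endpoint = "viability",
                       marker = "erythrosine",
                       assay_delay_h = 1,
                       T_lethal = 43,
                       rlc_alpha = 0.7, rlc_P_max = 120, rlc_I_opt = 600,
                       rlc_noise = 0.05,
                       rlc_ladder = c(22, 79, 218, 467, 812, 1336, 1890),
                       rlc_FM = 1000,
                       cyto_background = 0.05,
                       cyto_sdlog = 0.25,
                       climate_mean = 20, climate_seasonal = 5,
                       climate_diel = 5,
                       heatwave_days = integer(0),
                       heatwave_temp = 46, heatwave_hours = 2,
                       year_days = 365L, sample_step_s = 3600,
                       irradiance_peak = 2000, irradiance_seasonal = 0.3) {
  stopifnot(noise_sd >= 0, duplicates >= 1, n_times >= 4,
            rlc_noise >= 0, heatwave_hours > 0)
  structure(as.list(environment()), class = "gen_config")
}

#' Generate a replicated kinetic dataset
#'
#' Draws viability (or activity) fractions from the Weibull survival law
#' of `config$params` at each configured temperature, on a log-spaced
#' exposure grid scaled to that temperature's half-life (0.05 to 2
#' half-lives, so every supra-lethal curve decays through the
#' identifiable range). Temperatures below `T_lethal` produce flat curves
#' at fraction 1, mirroring the absence of loss at sub-lethal
#' temperatures. Independent Gaussian noise is added per replicate and
#' fractions are clamped to \[0, 1.05\].
#'
#' @param config A [gen_config()].
#' @return A tibble with columns `temperature_C`, `time_s`, `replicate`,
#'   `fraction`, `endpoint`, `marker`, `assay_delay_h`.
#' @export
gen_kinetics <- function(config) {
  stopifnot(inherits(config, "gen_config"))
  set.seed(as.integer(config$seed))
  p <- config$params
  rows <- purrr::map_dfr(config$temperatures, function(Tc) {
    if (Tc >= config$T_lethal) {
      lam <- half_life(Tc, p)
      times <- exp(seq(log(0.05 * lam), log(2 * lam),
                       length.out = config$n_times))
      truth <- weibull_survival(times, Tc, p)
    } else {
      times <- exp(seq(log(30), log(10800), length.out = config$n_times))
      truth <- rep(1, config$n_times)
    }
    tidyr::expand_grid(time_s = times, replicate = seq_len(config$duplicates)) |>
      dplyr::mutate(temperature_C = Tc,
                    fraction = truth[match(.data$time_s, times)])
  })
  rows$fraction <- pmin(1.05, pmax(0, rows$fraction +
                                     config$noise_sd * stats::rnorm(nrow(rows))))
  dplyr::select(rows, "temperature_C", "time_s", "replicate", "fraction") |>
    dplyr::mutate(endpoint = config$endpoint, marker = config$marker,
                  assay_delay_h = config$assay_delay_h)
}

#' Generate rapid-light-curve records
#'
#' Builds `n` PAM light curves on the configured irradiance ladder from
#' the reparameterised Eilers-Peeters truth: the model quantum yield at
#' each step is `rETR_model(I)/I`, the fluorescence pair is
#' `F = FM' (1 - Phi)` at constant `FM'`, and multiplicative noise is
#' applied to `F`. `alpha_scale` rescales the true initial slope (e.g.
#' to emulate heat-stressed samples against a control).
#'
#' @param config A [gen_config()].
#' @param n Number of samples.
#' @param alpha_scale Scaling of the true alpha per sample (recycled).
#' @return A tibble `sample_id`, `irradiance`, `F`, `FM_prime`.
#' @export
gen_rlc <- function(config, n = 1L, alpha_scale = 1) {
  stopifnot(inherits(config, "gen_config"))
  set.seed(as.integer(config$seed) + 1L)
  alpha_scale <- rep_len(alpha_scale, n)
  purrr::map_dfr(seq_len(n), function(i) {
    I <- config$rlc_ladder
    mod <- eilers_peeters(I, config$rlc_alpha * alpha_scale[i],
                          config$rlc_P_max, config$rlc_I_opt)
    phi <- ifelse(I > 0, mod / I, 0)
    phi <- pmin(phi, 0.999)
    F_ <- config$rlc_FM * (1 - phi)
    F_ <- F_ * (1 + config$rlc_noise * stats::rnorm(length(F_)))
    F_ <- pmin(pmax(F_, 1e-3), config$rlc_FM * (1 - 1e-6))
    tibble::tibble(sample_id = i, irradiance = I, F = F_,
                   FM_prime = config$rlc_FM)
  })
}

#' Generate a three-channel cytometry event table
#'
#' Draws algal events with a high log-normal chlorophyll (`FL3`) mode and
#' a configurable non-algal background with a low mode. Dead algal cells
#' get the high erythrosine (`FL2`) mode and the low FDA (`FL1`) mode;
#' live cells the reverse - both stains are generated consistently from
#' the same underlying label, so the two gating modes agree on noiseless
#' separation.
#'
#' @param viability True live fraction among algal events, in \[0, 1\].
#' @param n_events Total events to draw.
#' @param config A [gen_config()].
#' @return A tibble `FL1`, `FL2`, `FL3`, `true_label`.
#' @export
gen_cytometry <- function(viability, n_events = 5000L, config = gen_config()) {
  stopifnot(viability >= 0, viability <= 1, n_events >= 1)
  set.seed(as.integer(config$seed) + 2L)
  n_bg <- stats::rbinom(1L, n_events, config$cyto_background)
  n_algal <- n_events - n_bg
  n_live <- stats::rbinom(1L, n_algal, viability)
  lab <- c(rep("non-algal", n_bg), rep("live", n_live),
           rep("dead", n_algal - n_live))
  lab <- sample(lab)
  n <- length(lab)
  draw <- function(meanlog) stats::rlnorm(n, meanlog, config$cyto_sdlog)
  hi <- log(1000); lo <- log(5)
  FL3 <- ifelse(lab == "non-algal", draw(lo), draw(hi))
  FL2 <- ifelse(lab == "dead", draw(hi), draw(lo))        # erythrosine uptake
  FL1 <- ifelse(lab == "live", draw(hi), draw(lo))        # FDA hydrolysis
  tibble::tibble(FL1 = FL1, FL2 = FL2, FL3 = FL3, true_label = lab)
}

#' Generate a killed/fresh mixing series for gating validation
#'
#' Emulates the validation experiment: a heat-killed stock (viability 0,
#' partially degraded so its cell concentration is lower) mixed with a
#' fresh stock at nominal killed volume fractions, with the measured
#' viability generated around the count-corrected expectation.
#'
#' @param config A [gen_config()].
#' @param volume_fractions Nominal killed-stock volume fractions.
#' @param C_heated,C_fresh Stock cell concentrations (cells per mL).
#' @param noise_sd Gaussian noise sd on measured viability.
#' @param replicates Measurements per mixing level.
#' @return A tibble `volume_fraction`, `C_heated`, `C_fresh`,
#'   `expected_viability`, `measured_viability`.
#' @export
gen_mix_series <- function(config = gen_config(),
                           volume_fractions = c(0, 0.25, 0.5, 0.75, 1),
                           C_heated = 8e3, C_fresh = 1e4,
                           noise_sd = 0.02, replicates = 3L) {
  set.seed(as.integer(config$seed) + 3L)
  grid <- tidyr::expand_grid(volume_fraction = volume_fractions,
                             rep = seq_len(replicates))
  expected <- 1 - corrected_killed_fraction(grid$volume_fraction,
                                            C_heated, C_fresh)
  tibble::tibble(
    volume_fraction = grid$volume_fraction,
    C_heated = C_heated, C_fresh = C_fresh,
    expected_viability = expected,
    measured_viability = pmin(1, pmax(0, expected +
                                        noise_sd * stats::rnorm(nrow(grid)))))
}

#' Generate a synthetic climate record
#'
#' Hourly (by default) temperature and irradiance over a year:
#' temperature is an annual mean plus a seasonal cosine (peaking at day
#' 0), a diel cycle peaking mid-afternoon, and optional injected heatwave
#' plateaus on selected days; irradiance is a clear-sky half-sine between
#' 06:00 and 18:00 with optional seasonal modulation of the midday peak.
#' Heatwave plateaus run from 12:00 for the configured number of hours.
#'
#' @param config A [gen_config()].
#' @return A tibble `time_s`, `temp_C`, `irradiance`.
#' @export
gen_climate <- function(config) {
  stopifnot(inherits(config, "gen_config"))
  set.seed(as.integer(config$seed) + 4L)
  time_s <- seq(0, config$year_days * 86400, by = config$sample_step_s)
  day <- floor(time_s / 86400)
  hour <- (time_s %% 86400) / 3600
  temp <- config$climate_mean +
    config$climate_seasonal * cos(2 * pi * day / 365) +
    config$climate_diel * cos(2 * pi * (hour - 14) / 24)
  if (length(config$heatwave_days) > 0) {
    in_spike <- day %in% config$heatwave_days &
      hour >= 12 & hour <= 12 + config$heatwave_hours
    temp[in_spike] <- pmax(temp[in_spike], config$heatwave_temp)
  }
  peak <- config$irradiance_peak *
    (1 + config$irradiance_seasonal * cos(2 * pi * day / 365))
  irr <- ifelse(hour > 6 & hour < 18,
                peak * sin(pi * (hour - 6) / 12), 0)
  tibble::tibble(time_s = time_s, temp_C = temp, irradiance = pmax(0, irr))
}
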