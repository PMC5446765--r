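test_that("mortality events are contiguous supra-lethal periods", {
  cool <- constant_series(30, 86400, by = 3600)
  expect_equal(nrow(detect_mortality_events(cool)), 0)
  hot <- constant_series(45, 7200, by = 600)
  ev <- detect_mortality_events(hot)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$dose_V, 2.5214554769299387, tolerance = 1e-9)
  expect_gt(ev$dose_A, ev$dose_V)
})

test_that("triangular spikes get interpolated boundaries and accurate doses", {
  tri <- function(by) {
    tt <- seq(0, 4 * 3600, by = by)
    peak <- 2 * 3600
    data.frame(time_s = tt, temp_C = 30 + 17 * pmax(0, 1 - abs(tt - peak) / peak))
  }
  ev <- detect_mortality_events(tri(600))
  expect_equal(nrow(ev), 1)
  # crossing times of the 43 degC threshold, known analytically
  expect_equal(ev$t_s, 2 * 3600 * 13 / 17, tolerance = 1e-6)
  expect_equal(ev$t_e, 2 * 3600 * (2 - 13 / 17), tolerance = 1e-6)
  ref <- detect_mortality_events(tri(10))
  expect_equal(ev$dose_V, ref$dose_V, tolerance = 0.01)
})

test_that("events multiply fractions through the dose powers and never recover", {
  cfg <- sim_config()
  st <- culture_state()
  expect_identical(apply_event(st, list(dose_V = 0, dose_A = 0), cfg), st)
  st1 <- apply_event(st, list(dose_V = 1, dose_A = 0), cfg)
  expect_equal(st1$f_V, exp(-1))
  expect_equal(st1$f_A, 1)
  # two consecutive events equal one merged event with summed doses
  a <- apply_event(apply_event(st, list(dose_V = 0.6, dose_A = 1.1), cfg),
                   list(dose_V = 0.9, dose_A = 0.4), cfg)
  merged <- apply_event(st, list(dose_V = 1.5, dose_A = 1.5), cfg)
  expect_equal(a$f_V, exp(-0.6^cfg$viability_params$n) *
                 exp(-0.9^cfg$viability_params$n))
  expect_equal(merged$f_V, exp(-1.5^cfg$viability_params$n))
  # sequential application under-kills relative to the merged dose (n > 1)
  expect_gt(a$f_V, merged$f_V)
})

test_that("activity dose dominates viability dose across the lethal range", {
  Ts <- seq(43, 60, by = 0.5)
  dV <- thermal_dose_constant(1, Ts, params_erythrosine())
  dA <- thermal_dose_constant(1, Ts, params_activity())
  expect_true(all(dA >= dV))
})

test_that("growth is exact exponential with pluggable temperature response", {
  gm <- growth_model(mu = log(2) / 86400)
  st <- culture_state(biomass = 1e10)
  expect_equal(grow(st, 86400, 25, gm)$biomass, 2e10)
  expect_equal(grow(st, 5000, 25, growth_model(mu = 0))$biomass, 1e10)
  gm2 <- growth_model(mu = 1e-5, phi = function(T) ifelse(T > 30, 0, 1))
  expect_equal(grow(st, 1000, 35, gm2)$biomass, 1e10)
})

test_that("a benign year produces no collapses and no light loss", {
  cfg <- gen_config(seed = 51, climate_mean = 20, climate_seasonal = 5,
                    climate_diel = 5)
  clim <- gen_climate(cfg)
  res <- run_simulation(clim, config = sim_config())
  expect_equal(res$summary$collapse_days, 0)
  expect_equal(res$summary$deactivation_days, 0)
  expect_equal(res$summary$days_over_lethal, 0)
  expect_equal(res$summary$light_loss_fraction, 0)
  expect_true(all(res$daily$f_V == 1))
})

test_that("each injected supra-lethal spike day collapses the culture once", {
  spikes <- c(60, 140, 220, 300)
  cfg <- gen_config(seed = 52, heatwave_days = spikes, heatwave_temp = 46,
                    heatwave_hours = 2)
  clim <- gen_climate(cfg)
  res <- run_simulation(clim, config = sim_config(policy = "next-sunrise"))
  expect_equal(res$summary$collapse_days, length(spikes))
  expect_equal(res$summary$deactivation_days, length(spikes))
  expect_equal(res$summary$days_over_lethal, length(spikes))
  expect_equal(sort(res$daily$day[res$daily$collapse]), spikes)
  # per-day light bookkeeping: lost fraction equals the lost days' light share
  daily <- res$daily
  expect_equal(res$summary$light_loss_fraction,
               sum(daily$light[daily$lost_light]) / sum(daily$light),
               tolerance = 1e-12)
  expect_equal(sum(daily$lost_light), length(spikes))
})

test_that("viable and active fractions never increase between re-inoculations", {
  cfg <- gen_config(seed = 53, heatwave_days = c(100, 200),
                    heatwave_temp = 44.2, heatwave_hours = 1)
  res <- run_simulation(gen_climate(cfg), config = sim_config())
  d <- res$daily
  reinoc <- c(TRUE, d$f_V[-1] > d$f_V[-nrow(d)] + 1e-12)
  # any increase must coincide with a re-inoculation from a collapsed state
  rising <- which(reinoc[-1]) + 1
  if (length(rising) > 0) {
    expect_true(all(d$status[rising - 1] != "growing" | d$collapse[rising - 1]))
  }
  expect_true(all(d$f_A <= d$f_V + 1e-12))
})

test_that("the delayed re-inoculation policy books the idle days' light as lost", {
  cfg <- gen_config(seed = 54, heatwave_days = 180, irradiance_seasonal = 0)
  clim <- gen_climate(cfg)
  res <- run_simulation(clim,
                        config = sim_config(policy = "delay-days",
                                            delay_days = 5))
  expect_equal(res$summary$collapse_days, 1)
  daily <- res$daily
  expect_equal(sum(daily$lost_light), 6)  # the collapse day plus 5 idle days
  expect_equal(res$summary$light_loss_fraction,
               sum(daily$light[daily$lost_light]) / sum(daily$light),
               tolerance = 1e-12)
  # with constant daily light that share is 6/365 up to the daily totals
  expect_equal(res$summary$light_loss_fraction, 6 / 365, tolerance = 1e-6)
  # the policy only changes light accounting, not the collapse count
  res_ns <- run_simulation(clim, config = sim_config(policy = "next-sunrise"))
  expect_equal(res_ns$summary$collapse_days, res$summary$collapse_days)
  expect_equal(sum(res_ns$daily$lost_light), 1)
})

test_that("an infinite lethal threshold reduces to pure growth", {
  cfg <- gen_config(seed = 55, heatwave_days = c(50, 150))
  clim <- gen_climate(cfg)
  gm <- growth_model(mu = log(2) / 86400)
  res <- run_simulation(clim, config = sim_config(T_lethal = Inf), growth = gm)
  expect_equal(res$summary$collapse_days, 0)
  expect_true(all(res$daily$f_V == 1))
  n_days <- nrow(res$daily)
  expect_equal(res$daily$biomass[n_days],
               sim_config()$inoculum * 2^n_days, tolerance = 1e-6)
})

test_that("dose totals are stable under finer sampling of a smooth profile", {
  # ten days of a smooth diel profile whose afternoons exceed 43 degC
  prof <- function(by) {
    tt <- seq(0, 10 * 86400, by = by)
    data.frame(time_s = tt,
               temp_C = 38 + 8 * sin(2 * pi * (tt / 86400 - 0.35)))
  }
  d1 <- thermal_dose_series(prof(1200), erythrosine, threshold = 43)
  d2 <- thermal_dose_series(prof(600), erythrosine, threshold = 43)
  expect_lt(abs(d1 - d2) / d2, 0.005)
})

test_that("misaligned series are rejected and summaries surface as tibbles", {
  t1 <- data.frame(time_s = c(0, 3600, 7200) + 0, temp_C = 20)
  ir <- data.frame(time_s = c(0, 1800, 3600), irradiance = 100)
  expect_error(run_simulation(t1, ir), class = "thermodose_domain_error")
  cfg <- gen_config(seed = 57, year_days = 3L)
  res <- run_simulation(gen_climate(cfg), config = sim_config())
  expect_s3_class(glance(res), "tbl_df")
  expect_equal(productivity_loss(res), res$summary$light_loss_fraction)
})
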