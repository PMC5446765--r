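test_that("half-life law evaluates the exponential of temperature", {
  expect_equal(half_life(81.5, erythrosine), 1.0)
  # hand-computed exp(-0.218 * (T - 81.5))
  expect_equal(half_life(45, erythrosine), 2855.4936090985593, tolerance = 1e-12)
  expect_equal(half_life(60, erythrosine), 108.52710961783075, tolerance = 1e-12)
  # strictly decreasing in T for a < 0
  Ts <- seq(40, 65, by = 0.5)
  expect_true(all(diff(half_life(Ts, erythrosine)) < 0))
  expect_error(half_life(NaN, erythrosine), class = "thermodose_domain_error")
})

test_that("Weibull survival matches closed form and is monotone", {
  expect_equal(weibull_survival(0, 45, erythrosine), 1.0)
  # an exposure of one half-life kills 63% whatever the shape factor
  for (n in c(0.5, 1, 3, 4.84)) {
    p <- survival_params(-0.218, 81.5, n)
    expect_equal(weibull_survival(half_life(50, p), 50, p), exp(-1),
                 tolerance = 1e-12)
  }
  expect_equal(weibull_survival(3600, 45, erythrosine),
               0.046464235639461164, tolerance = 1e-10)
  tt <- seq(0, 8000, by = 100)
  expect_true(all(diff(weibull_survival(tt, 45, erythrosine)) <= 0))
  # non-increasing in temperature too
  expect_true(all(diff(weibull_survival(1800, seq(43, 60, 0.5), erythrosine)) <= 0))
  expect_error(weibull_survival(-1, 45, erythrosine),
               class = "thermodose_domain_error")
})

test_that("constant-temperature dose is time over half-life", {
  expect_equal(thermal_dose_constant(0, 45, erythrosine), 0)
  expect_equal(thermal_dose_constant(half_life(45, erythrosine), 45, erythrosine), 1)
  expect_equal(thermal_dose_constant(3600, 45, erythrosine),
               1.2607277384649693, tolerance = 1e-10)
  # linear in t
  expect_equal(thermal_dose_constant(7200, 45, erythrosine),
               2 * thermal_dose_constant(3600, 45, erythrosine))
})

test_that("series dose matches segment-wise closed forms", {
  s <- constant_series(45, 3600)
  expect_equal(thermal_dose_series(s, erythrosine),
               thermal_dose_constant(3600, 45, erythrosine), tolerance = 1e-12)
  # two-segment profile: 1800 s at 45 then 1800 s at 50 (step at a knot)
  s2 <- data.frame(time_s = c(0, 1799.9999, 1800, 3600),
                   temp_C = c(45, 45, 50, 50))
  expect_equal(thermal_dose_series(s2, erythrosine), 2.5052387817711983,
               tolerance = 1e-4)
  # entirely below threshold -> 0
  expect_equal(thermal_dose_series(constant_series(40, 7200), erythrosine,
                                   threshold = 43), 0)
  expect_error(thermal_dose_series(data.frame(time_s = 0, temp_C = 45),
                                   erythrosine),
               class = "thermodose_domain_error")
})

test_that("dose is additive over a partition of the time axis", {
  set.seed(42)
  tt <- seq(0, 7200, by = 60)
  s <- data.frame(time_s = tt, temp_C = 44 + 4 * sin(tt / 900) + rnorm(length(tt), 0, 0.2))
  whole <- thermal_dose_series(s, erythrosine)
  for (cut in c(10, 61, 100)) {
    left <- thermal_dose_series(s[1:cut, ], erythrosine)
    right <- thermal_dose_series(s[cut:nrow(s), ], erythrosine)
    expect_equal(left + right, whole, tolerance = 1e-10)
  }
})

test_that("survival_from_dose agrees with the constant-temperature form", {
  expect_equal(survival_from_dose(0, 4.84), 1.0)
  expect_equal(survival_from_dose(1, 0.7), exp(-1))
  expect_equal(survival_from_dose(1.2607277384649693, 4.84),
               weibull_survival(3600, 45, erythrosine), tolerance = 1e-10)
  s <- constant_series(45, 3600, by = 1)
  expect_equal(
    survival_from_dose(thermal_dose_series(s, erythrosine), erythrosine$n),
    weibull_survival(3600, 45, erythrosine), tolerance = 1e-6)
  expect_error(survival_from_dose(-0.1, 2), class = "thermodose_domain_error")
})

test_that("Weibull with n = 1 is the first-order model with m = 1/lambda", {
  p1 <- survival_params(-0.218, 81.5, 1)
  tt <- seq(0, 10000, by = 250)
  lam <- half_life(48, p1)
  expect_equal(weibull_survival(tt, 48, p1), first_order_survival(tt, 1 / lam),
               tolerance = 1e-12)
  expect_equal(first_order_survival(0, 2e-4), 1)
  expect_equal(first_order_survival(c(10, 5000), 0), c(1, 1))
  expect_equal(first_order_survival(1 / 3e-4, 3e-4), exp(-1))
})

test_that("trapezoidal dose converges at second order on smooth profiles", {
  profile <- function(by) {
    tt <- seq(0, 7200, by = by)
    data.frame(time_s = tt, temp_C = 45 + 5 * sin(pi * tt / 7200))
  }
  exact <- thermal_dose_series(profile(0.5), erythrosine)
  err <- vapply(c(600, 300, 150), function(by) {
    abs(thermal_dose_series(profile(by), erythrosine) - exact)
  }, numeric(1))
  order_obs <- log2(err[1] / err[2])
  expect_gt(order_obs, 1.9)
  expect_gt(log2(err[2] / err[3]), 1.9)
})

test_that("Geeraerd model reduces, saturates and shoulders as expected", {
  tt <- seq(0, 20000, by = 100)
  # Cc0 = 0, N_res = 0 collapses to first-order
  g <- geeraerd_survival(tt, m_m = 5e-4, Cc0 = 0, N_res = 0)
  expect_equal(g$N, first_order_survival(tt, 5e-4), tolerance = 1e-6)
  # N0 = N_res gives a constant curve
  g2 <- geeraerd_survival(tt, m_m = 5e-4, Cc0 = 10, N_res = 1, N0 = 1)
  expect_equal(g2$N, rep(1, length(tt)), tolerance = 1e-8)
  # closed-form oracle for N_res = 0:
  #   N(t) = N0 exp(-mt) (1 + Cc0) / (1 + Cc0 exp(-mt))
  m <- 1e-3; Cc0 <- 100
  tt3 <- seq(0, 15000, by = 50)
  g3 <- geeraerd_survival(tt3, m_m = m, Cc0 = Cc0, N_res = 0)
  oracle <- exp(-m * tt3) * (1 + Cc0) / (1 + Cc0 * exp(-m * tt3))
  expect_equal(g3$N, oracle, tolerance = 1e-6)
  # shoulder lasts about ln(Cc0)/m before log-linear decay: survival is
  # still > 80% at half the shoulder time and < 10% by twice that time
  shoulder <- log(Cc0) / m
  expect_gt(oracle[which.min(abs(tt3 - shoulder / 2))], 0.8)
  expect_lt(oracle[which.min(abs(tt3 - 2 * shoulder))], 0.1)
  expect_true(all(diff(g3$N) <= 1e-12))
})

test_that("log-logistic curve has the stated plateaus and midpoint", {
  al <- 0; om <- -9; sg <- -2; ta <- 3
  expect_equal(log_logistic_survival(1e-15, al, om, sg, ta), exp(al),
               tolerance = 1e-5)
  expect_equal(log_logistic_survival(1e30, al, om, sg, ta), exp(om),
               tolerance = 1e-5)
  expect_equal(log_logistic_survival(10^ta, al, om, sg, ta),
               exp((al + om) / 2), tolerance = 1e-12)
  expect_error(log_logistic_survival(0, al, om, sg, ta),
               class = "thermodose_domain_error")
  # natural-log variant shifts the midpoint to exp(tau)
  expect_equal(log_logistic_survival(exp(ta), al, om, sg, ta, log_base = exp(1)),
               exp((al + om) / 2), tolerance = 1e-12)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(survival_params(-0.2, 80, -1), class = "thermodose_domain_error")
  expect_error(survival_params(NA_real_, 80, 2), class = "thermodose_domain_error")
  p <- params_fda()
  expect_equal(c(p$a, p$T0, p$n), c(-0.232, 80.1, 5.59))
  expect_equal(params_activity()$endpoint, "activity")
})
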