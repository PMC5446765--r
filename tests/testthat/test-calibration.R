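test_that("noise-free Weibull fits recover the generating parameters", {
  for (truth in list(c(lambda = 2856, n = 4.84), c(lambda = 500, n = 1.2),
                     c(lambda = 5e4, n = 9))) {
    curve <- make_weibull_curve(truth[["lambda"]], truth[["n"]])
    fit <- fit_weibull_kinetic(curve, temperature = 45)
    expect_equal(fit$lambda_hat, truth[["lambda"]], tolerance = 1e-6)
    expect_equal(fit$n_hat, truth[["n"]], tolerance = 1e-6)
  }
})

test_that("curves without decay are rejected as unidentifiable", {
  flat <- data.frame(time_s = c(100, 500, 2000, 8000), fraction = rep(1, 4))
  err <- expect_error(fit_weibull_kinetic(flat, temperature = 41),
                      class = "thermodose_insufficient_decay")
  expect_match(conditionMessage(err), "41")
  short <- data.frame(time_s = c(100, 500, 2000), fraction = c(1, 0.5, 0.1))
  expect_error(fit_weibull_kinetic(short, temperature = 45),
               class = "thermodose_domain_error")
})

test_that("half-life estimation is robust to duplicate noise", {
  ok <- 0L
  for (i in 1:200) {
    set.seed(5000 + i)
    curve <- make_weibull_curve(2856, 4.84, n_times = 8)
    curve <- curve[rep(seq_len(nrow(curve)), each = 2), ]
    curve$fraction <- pmax(0, curve$fraction + rnorm(nrow(curve), 0, 0.03))
    fit <- tryCatch(fit_weibull_kinetic(curve, temperature = 45),
                    error = function(e) NULL)
    if (!is.null(fit) && abs(fit$lambda_hat / 2856 - 1) < 0.1) ok <- ok + 1L
  }
  expect_gte(ok, 180L)
})

test_that("half-life regression recovers the exponential law exactly", {
  fits <- lapply(c(43, 45, 50, 60), function(Tc) {
    structure(list(temperature = Tc,
                   lambda_hat = half_life(Tc, erythrosine),
                   n_hat = 4.84, rss = 0, converged = TRUE,
                   se_lambda = 1, se_n = 0.1, n_obs = 8),
              class = "weibull_fit")
  })
  reg <- fit_halflife_temperature(fits)
  expect_equal(reg$a, -0.218, tolerance = 1e-12)
  expect_equal(reg$T0, 81.5, tolerance = 1e-12)
  expect_gt(reg$r_squared, 1 - 1e-12)
  expect_length(reg$outliers, 0)
  expect_error(fit_halflife_temperature(fits[1:2]),
               class = "thermodose_domain_error")
})

test_that("regression diagnostics flag a gross outlier", {
  fits <- lapply(c(43, 45, 47, 50, 55, 60), function(Tc) {
    lam <- half_life(Tc, erythrosine) * ifelse(Tc == 47, 150, 1)
    structure(list(temperature = Tc, lambda_hat = lam, n_hat = 4.84,
                   rss = 0, converged = TRUE, se_lambda = 1, se_n = 0.1,
                   n_obs = 8),
              class = "weibull_fit")
  })
  expect_true(47 %in% fit_halflife_temperature(fits)$outliers)
})

test_that("shape factors pool by plain or inverse-variance mean", {
  mk <- function(n_hat, se_n) {
    structure(list(temperature = 45, lambda_hat = 1000, n_hat = n_hat,
                   rss = 0, converged = TRUE, se_lambda = 1, se_n = se_n,
                   n_obs = 8),
              class = "weibull_fit")
  }
  expect_equal(average_shape(list(mk(5, 1), mk(5, 2), mk(5, 3))), 5)
  expect_equal(average_shape(list(mk(4, 1), mk(5, 1), mk(6, 1))), 5)
  # heteroscedastic fits: precision weighting pulls toward the precise fit
  w <- average_shape(list(mk(4, 0.1), mk(6, 1)), weighted = TRUE)
  expect_equal(w, (4 / 0.01 + 6 / 1) / (1 / 0.01 + 1 / 1))
  expect_lt(w, 4.1)
})

test_that("two-stage calibration recovers generator truth on all marker laws", {
  for (truth in list(params_erythrosine(), params_fda(), params_activity())) {
    cfg <- gen_config(seed = 11, params = truth, noise_sd = 0,
                      temperatures = c(43, 45, 50, 60), n_times = 10)
    res <- calibrate(gen_kinetics(cfg))
    expect_equal(res$params$a, truth$a, tolerance = 1e-4)
    expect_equal(res$params$T0, truth$T0, tolerance = 1e-4)
    expect_equal(res$params$n, truth$n, tolerance = 1e-4)
  }
})

test_that("a sub-lethal-only dataset fails calibration with a clear error", {
  cfg <- gen_config(seed = 12, noise_sd = 0.02, temperatures = c(41, 42))
  expect_error(calibrate(gen_kinetics(cfg)),
               class = "thermodose_insufficient_decay")
  # full default grid: 41/42 are excluded but calibration succeeds
  res <- calibrate(gen_kinetics(gen_config(seed = 13, noise_sd = 0)))
  expect_setequal(res$excluded, c("41", "42"))
  expect_equal(res$params$a, -0.218, tolerance = 1e-3)
})

test_that("calibrated a and T0 transform correctly under unit changes", {
  cfg <- gen_config(seed = 14, noise_sd = 0, temperatures = c(43, 45, 50, 60),
                    n_times = 8)
  d <- gen_kinetics(cfg)
  res <- calibrate(d)
  # time rescaling: minutes instead of seconds shifts lambda by 60,
  # leaving a unchanged and T0 shifted by log(60)/a
  d_min <- dplyr::mutate(d, time_s = time_s / 60)
  res_min <- calibrate(d_min)
  expect_equal(res_min$params$a, res$params$a, tolerance = 1e-6)
  expect_equal(res_min$params$T0, res$params$T0 + log(60) / res$params$a,
               tolerance = 1e-6)
  # uniform temperature offset shifts T0 by the same amount
  d_off <- dplyr::mutate(d, temperature_C = temperature_C + 2)
  res_off <- calibrate(d_off)
  expect_equal(res_off$params$T0, res$params$T0 + 2, tolerance = 1e-6)
  expect_equal(res_off$params$a, res$params$a, tolerance = 1e-6)
})

test_that("duplicate differences pool into a measurement sd", {
  d <- data.frame(temperature_C = rep(45, 4), time_s = rep(c(100, 200), each = 2),
                  replicate = rep(1:2, 2), fraction = c(0.8, 0.8, 0.5, 0.5))
  expect_equal(duplicate_sd(d), 0)
  d1 <- data.frame(temperature_C = 45, time_s = c(100, 100),
                   replicate = 1:2, fraction = c(0.5, 0.6))
  expect_equal(duplicate_sd(d1), 0.07071067811865477, tolerance = 1e-12)
  # invariant to the order of the pair
  d2 <- d1[2:1, ]; d2$replicate <- 1:2
  expect_equal(duplicate_sd(d2), duplicate_sd(d1))
})

test_that("Monte-Carlo intervals are seeded and degenerate at zero noise", {
  cfg <- gen_config(seed = 15, noise_sd = 0.03,
                    temperatures = c(43, 45, 50, 60), n_times = 8)
  d <- gen_kinetics(cfg)
  r1 <- calibrate(d, mc_iter = 50, seed = 99)
  r2 <- calibrate(d, mc_iter = 50, seed = 99)
  expect_identical(r1$ci, r2$ci)
  expect_true(all(r1$ci$lower < r1$ci$upper))
  expect_true(all(r1$ci$lower <= tidy(r1)$estimate &
                    tidy(r1)$estimate <= r1$ci$upper))
  r0 <- calibrate(d, mc_iter = 20, seed = 1, noise_sd = 0)
  expect_equal(r0$ci$lower, r0$ci$upper)
})

test_that("interval width shrinks roughly as one over sqrt(replication)", {
  width_at <- function(dups) {
    cfg <- gen_config(seed = 16, noise_sd = 0.03, duplicates = dups,
                      temperatures = c(43, 45, 50, 60), n_times = 8)
    r <- calibrate(gen_kinetics(cfg), mc_iter = 150, seed = 17)
    diff(unlist(r$ci[r$ci$parameter == "a", c("lower", "upper")]))
  }
  ratio <- width_at(8) / width_at(2)
  # expected 1/2; allow generous stochastic slack
  expect_gt(ratio, 0.3)
  expect_lt(ratio, 0.75)
})

test_that("model comparison identifies the generating model", {
  set.seed(18)
  curve <- make_weibull_curve(2856, 4.84, n_times = 10)
  curve$fraction <- pmax(0, curve$fraction + rnorm(10, 0, 0.03))
  tbl <- compare_models(curve, temperature = 45)
  expect_setequal(tbl$model,
                  c("first-order", "weibull", "geeraerd", "log-logistic"))
  expect_lt(tbl$aic[tbl$model == "weibull"],
            tbl$aic[tbl$model == "first-order"])
  expect_true(all(is.finite(tbl$aic[tbl$converged])))
  expect_true(all(tbl$aicc >= tbl$aic))
  # first-order data: the fitted Weibull shape collapses to about 1
  set.seed(19)
  tt <- exp(seq(log(100), log(8000), length.out = 10))
  d1 <- data.frame(time_s = tt,
                   fraction = pmax(0, exp(-tt / 2000) + rnorm(10, 0, 0.03)))
  f <- fit_weibull_kinetic(d1, temperature = 45)
  expect_lt(abs(f$n_hat - 1), 0.35)
  # no-decay input is rejected before any fitting
  expect_error(compare_models(data.frame(time_s = c(1, 2, 3, 4) * 100,
                                         fraction = rep(1, 4))),
               class = "thermodose_insufficient_decay")
})

test_that("tidiers expose calibration results as tibbles", {
  cfg <- gen_config(seed = 20, noise_sd = 0, temperatures = c(43, 45, 50, 60),
                    n_times = 8)
  res <- calibrate(gen_kinetics(cfg))
  td <- tidy(res)
  expect_equal(td$term, c("a", "T0", "n"))
  expect_equal(td$estimate[1], -0.218, tolerance = 1e-3)
  gl <- glance(res)
  expect_equal(gl$n_temperatures, 4L)
  expect_s3_class(tidy(res$fit_objects[[1]]), "tbl_df")
})
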