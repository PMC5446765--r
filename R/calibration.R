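#' @keywords internal
check_kinetic_curve <- function(data, temperature = NULL) {
  if (!is.data.frame(data) || !all(c("time_s", "fraction") %in% names(data))) {
    rlang::abort("A kinetic curve needs columns `time_s` and `fraction`.",
                 class = "thermodose_domain_error")
  }
  if (is.null(temperature) && "temperature_C" %in% names(data)) {
    temps <- unique(data$temperature_C)
    if (length(temps) != 1L) {
      rlang::abort("`data` holds several temperatures; subset to one or call `calibrate()`.",
                   class = "thermodose_domain_error")
    }
    temperature <- temps
  }
  if (length(unique(data$time_s)) < 4L) {
    rlang::abort("Need at least 4 distinct exposure times to fit the Weibull model.",
                 class = "thermodose_domain_error")
  }
  if (min(data$fraction) >= 0.5) {
    rlang::abort(
      sprintf(paste0("Insufficient decay at %s degC: no measured fraction fell below 0.5, ",
                     "so the half-life is not identifiable."),
              if (is.null(temperature)) "this temperature" else format(temperature)),
      class = "thermodose_insufficient_decay")
  }
  temperature
}

# Log-log linearisation of the Weibull survival: ln(-ln V) = n ln t - n ln lambda,
# used to initialise the nonlinear fit from points strictly inside (0, 1).
weibull_linearised_start <- function(time_s, fraction) {
  ok <- fraction > 1e-10 & fraction < 1 - 1e-10 & time_s > 0
  if (sum(ok) >= 2L) {
    fit <- stats::lm(log(-log(fraction[ok])) ~ log(time_s[ok]))
    n0 <- unname(stats::coef(fit)[2L])
    l0 <- exp(-unname(stats::coef(fit)[1L]) / n0)
    if (is.finite(n0) && is.finite(l0) && n0 > 0 && l0 > 0) {
      return(c(lambda = l0, n = min(max(n0, 0.1), 20)))
    }
  }
  # fall back: time whose fraction is nearest exp(-1) approximates lambda
  l0 <- time_s[which.min(abs(fraction - exp(-1)))]
  c(lambda = max(l0, 1e-6), n = 2)
}

# RSS of the Weibull survival curve in log-parameters, with analytic gradient;
# the fast path used inside Monte-Carlo loops.
weibull_rss_obj <- function(theta, time_s, fraction) {
  lambda <- exp(theta[1L]); n <- exp(theta[2L])
  u <- time_s / lambda
  un <- u^n
  S <- exp(-un)
  r <- fraction - S
  rss <- sum(r^2)
  dS_dloglambda <- S * n * un
  lu <- ifelse(time_s > 0, log(u), 0)
  dS_dlogn <- -S * un * n * lu
  grad <- c(-2 * sum(r * dS_dloglambda), -2 * sum(r * dS_dlogn))
  list(value = rss, gradient = grad)
}

fit_weibull_optim <- function(time_s, fraction, start) {
  theta0 <- log(unname(start))
  fn <- function(th) weibull_rss_obj(th, time_s, fraction)$value
  gr <- function(th) weibull_rss_obj(th, time_s, fraction)$gradient
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      lower = c(-30, log(0.1)), upper = c(30, log(20)),
                      control = list(maxit = 200, factr = 1e4))
  list(lambda = exp(opt$par[1L]), n = exp(opt$par[2L]),
       rss = opt$value, converged = opt$convergence == 0)
}

fit_weibull_nls <- function(time_s, fraction, start) {
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fraction ~ exp(-(time_s / lambda)^n),
      start = list(lambda = start[["lambda"]], n = start[["n"]]),
      lower = c(lambda = 1e-9, n = 0.1), upper = c(lambda = Inf, n = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(lambda = NA_real_, n = NA_real_))
  list(lambda = unname(cf[["lambda"]]), n = unname(cf[["n"]]),
       rss = sum(stats::resid(fit)^2), converged = fit$convInfo$isConv %||% TRUE,
       se_lambda = unname(se[["lambda"]]), se_n = unname(se[["n"]]))
}

# Gauss-Newton standard errors from the analytic Jacobian, for the fast path.
weibull_param_se <- function(time_s, fraction, lambda, n, rss) {
  u <- time_s / lambda
  un <- u^n
  S <- exp(-un)
  J <- cbind(lambda = S * n * un / lambda,
             n = -S * un * ifelse(time_s > 0, log(u), 0))
  dof <- length(time_s) - 2L
  V <- tryCatch(solve(crossprod(J)) * rss / max(dof, 1L),
                error = function(e) matrix(NA_real_, 2, 2))
  sqrt(pmax(diag(V), 0))
}

#' Fit the Weibull survival model to one constant-temperature kinetic curve
#'
#' Bounded nonlinear least squares of \eqn{V(t) = \exp(-(t/\lambda)^n)} on
#' the fraction scale, initialised from the log-log linearisation
#' \eqn{\ln(-\ln V) = n \ln t - n \ln \lambda} and protected against
#' shape-factor local minima by a three-point multi-start
#' (linearisation, n = 1, n = 8). Curves in which no fraction falls below
#' 0.5 are rejected: without substantial decay the half-life is not
#' identifiable.
#'
#' @param data Data frame with columns `time_s` and `fraction` (and
#'   optionally `temperature_C`, which must then be constant).
#' @param temperature Temperature label, degrees C; taken from
#'   `temperature_C` when present.
#' @param multi_start Use the three-start strategy (default). Turned off in
#'   resampling loops where the point fit provides a warm start.
#' @param start Optional named vector `c(lambda=, n=)` overriding the
#'   automatic initialisation.
#' @param method `"nls"` (Levenberg-Marquardt, with standard errors) or
#'   `"optim"` (bounded quasi-Newton on log-parameters; faster, used
#'   internally for Monte-Carlo resampling).
#' @return A `weibull_fit` object: a list with `temperature`, `lambda_hat`
#'   (s), `n_hat`, `rss`, `converged`, standard errors and the data size.
#' @examples
#' p <- params_erythrosine()
#' d <- data.frame(time_s = seq(500, 6000, length.out = 8))
#' d$fraction <- weibull_survival(d$time_s, 45, p)
#' fit_weibull_kinetic(d, temperature = 45)
#' @export
fit_weibull_kinetic <- function(data, temperature = NULL, multi_start = TRUE,
                                start = NULL, method = c("nls", "optim")) {
  method <- match.arg(method)
  temperature <- check_kinetic_curve(data, temperature)
  time_s <- data$time_s
  fraction <- data$fraction

  starts <- list()
  if (!is.null(start)) {
    starts <- list(c(lambda = start[["lambda"]], n = start[["n"]]))
  } else {
    s0 <- weibull_linearised_start(time_s, fraction)
    starts <- list(s0)
    if (multi_start) {
      starts <- c(starts, list(c(lambda = s0[["lambda"]], n = 1),
                               c(lambda = s0[["lambda"]], n = 8)))
    }
  }

  best <- NULL
  for (s in starts) {
    f <- if (method == "nls") fit_weibull_nls(time_s, fraction, s)
         else fit_weibull_optim(time_s, fraction, s)
    if (is.null(f)) next
    if (is.null(best) || f$rss < best$rss) best <- f
  }
  if (is.null(best) || !isTRUE(best$converged)) {
    rlang::abort(
      sprintf("Weibull fit did not converge at %s degC (starts tried: %d).",
              format(temperature %||% NA), length(starts)),
      class = "thermodose_fit_error")
  }
  if (is.null(best$se_lambda)) {
    se <- weibull_param_se(time_s, fraction, best$lambda, best$n, best$rss)
    best$se_lambda <- se[1L]; best$se_n <- se[2L]
  }
  structure(list(temperature = temperature, lambda_hat = best$lambda,
                 n_hat = best$n, rss = best$rss, converged = TRUE,
                 se_lambda = best$se_lambda, se_n = best$se_n,
                 n_obs = length(time_s)),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("<weibull_fit> T = %s degC: lambda = %.4g s, n = %.3g (RSS %.3g, %d obs)\n",
              format(x$temperature), x$lambda_hat, x$n_hat, x$rss, x$n_obs))
  invisible(x)
}

#' Regress fitted half-lives on temperature
#'
#' Second calibration stage: ordinary least squares of \eqn{\ln\hat\lambda}
#' on temperature. The slope is the exponential coefficient `a` and the
#' reference temperature is `T0 = -intercept/slope`. Points with
#' standardized residual above 3 are flagged as outliers.
#'
#' @param fits A list of `weibull_fit` objects (>= 3 temperatures).
#' @return A list with `a`, `T0`, `r_squared`, `se_slope`, `se_intercept`,
#'   the underlying `lm` fit, and an `outliers` vector of flagged
#'   temperatures.
#' @export
fit_halflife_temperature <- function(fits) {
  fits <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
  if (length(fits) < 3L) {
    rlang::abort("Need converged Weibull fits at >= 3 temperatures for the half-life regression.",
                 class = "thermodose_domain_error")
  }
  temp <- vapply(fits, `[[`, numeric(1), "temperature")
  llam <- log(vapply(fits, `[[`, numeric(1), "lambda_hat"))
  reg <- stats::lm(llam ~ temp)
  cf <- stats::coef(reg)
  # summary() warns on noise-free (numerically perfect) fits; harmless here
  sm <- suppressWarnings(summary(reg))
  a <- unname(cf[2L])
  # leave-one-out residuals are numerical noise on an exact fit; only
  # meaningful when the regression has real scatter
  rs <- if (sm$sigma > 1e-8) suppressWarnings(stats::rstudent(reg)) else
    rep(0, length(temp))
  list(a = a,
       T0 = -unname(cf[1L]) / a,
       r_squared = sm$r.squared,
       se_slope = sm$coefficients[2L, 2L],
       se_intercept = sm$coefficients[1L, 2L],
       fit = reg,
       temperatures = temp,
       outliers = temp[is.finite(rs) & abs(rs) > 3])
}

#' Average the per-temperature Weibull shape factors
#'
#' The shape factor does not vary systematically with temperature, so a
#' single value is taken across temperatures: the unweighted mean by
#' default, or an inverse-variance (1/SE^2) weighted mean.
#'
#' @param fits List of `weibull_fit` objects.
#' @param weighted Use inverse-variance weights from the per-fit standard
#'   errors of the shape factor.
#' @return The pooled shape factor.
#' @export
average_shape <- function(fits, weighted = FALSE) {
  fits <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
  if (length(fits) < 1L) {
    rlang::abort("Need at least one converged fit.", class = "thermodose_domain_error")
  }
  n_hat <- vapply(fits, `[[`, numeric(1), "n_hat")
  if (!weighted) return(mean(n_hat))
  se <- vapply(fits, function(f) f$se_n %||% NA_real_, numeric(1))
  if (any(!is.finite(se)) || any(se <= 0)) {
    rlang::abort("Weighted averaging needs finite positive shape-factor SEs for all fits.",
                 class = "thermodose_domain_error")
  }
  w <- 1 / se^2
  sum(w * n_hat) / sum(w)
}

#' Pooled measurement noise from duplicate observations
#'
#' Pooled standard deviation of a single measurement estimated from the
#' differences between duplicates: `sqrt(sum(d^2) / (2 m))` over the `m`
#' duplicate differences `d`. Each (temperature, exposure time) group
#' contributes the difference of its first two replicates.
#'
#' @param dataset Kinetic data with columns `temperature_C`, `time_s`,
#'   `replicate`, `fraction`.
#' @return The pooled measurement standard deviation (fraction scale).
#' @export
duplicate_sd <- function(dataset) {
  stopifnot(all(c("temperature_C", "time_s", "fraction") %in% names(dataset)))
  d <- dataset |>
    dplyr::group_by(.data$temperature_C, .data$time_s) |>
    dplyr::filter(dplyr::n() >= 2L) |>
    dplyr::summarise(d = .data$fraction[2L] - .data$fraction[1L], .groups = "drop")
  if (nrow(d) < 1L) {
    rlang::abort("Need at least one duplicate pair to pool a measurement sd.",
                 class = "thermodose_domain_error")
  }
  sqrt(sum(d$d^2) / (2 * nrow(d)))
}

calibrate_point <- function(dataset, min_decay = 0.5, fast = FALSE,
                            warm_starts = NULL) {
  temps <- sort(unique(dataset$temperature_C))
  fits <- list()
  excluded <- character(0)
  for (Tc in temps) {
    sub <- dataset[dataset$temperature_C == Tc, , drop = FALSE]
    key <- format(Tc)
    f <- tryCatch(
      fit_weibull_kinetic(
        sub, temperature = Tc,
        multi_start = !fast,
        start = if (!is.null(warm_starts)) warm_starts[[key]] else NULL,
        method = if (fast) "optim" else "nls"),
      thermodose_insufficient_decay = function(e) e,
      thermodose_fit_error = function(e) e)
    if (inherits(f, "condition")) {
      excluded <- c(excluded, key)
    } else {
      fits[[key]] <- f
    }
  }
  if (length(fits) == 0L) {
    rlang::abort(
      "Insufficient decay at every temperature: viability never fell below 50%, nothing to calibrate.",
      class = "thermodose_insufficient_decay")
  }
  if (length(fits) < 3L) {
    rlang::abort(
      sprintf("Only %d temperature(s) passed the identifiability guard; >= 3 are needed (excluded: %s).",
              length(fits), paste(excluded, collapse = ", ")),
      class = "thermodose_insufficient_decay")
  }
  reg <- fit_halflife_temperature(fits)
  list(fits = fits, excluded = excluded, regression = reg,
       a = reg$a, T0 = reg$T0, n = average_shape(fits))
}

#' Two-stage calibration of the thermal-dose Weibull law
#'
#' Runs the full calibration: (1) per-temperature bounded least-squares
#' Weibull fits on the fraction scale, dropping temperatures where the
#' fraction never falls below 0.5 (no identifiable half-life; in the
#' source data this is the case below 43 degC); (2) log-linear regression
#' of the fitted half-lives on temperature giving the exponential
#' coefficient `a` and reference temperature `T0`; the shape factor `n` is
#' the unweighted mean across temperatures. Optionally attaches
#' Monte-Carlo 95% confidence intervals based on the duplicate-derived
#' measurement noise.
#'
#' @param dataset Kinetic data: `temperature_C`, `time_s`, `replicate`,
#'   `fraction` (plus optional metadata columns `endpoint`, `marker`,
#'   `assay_delay_h`).
#' @param endpoint Endpoint label for the returned parameter set.
#' @param mc_iter Monte-Carlo iterations for confidence intervals; 0 skips
#'   the uncertainty stage.
#' @param seed Seed for the Monte-Carlo stage.
#' @param noise_sd Measurement sd used by the Monte-Carlo stage; estimated
#'   from duplicates when `NULL`.
#' @return A `calibration_result`: the fitted [survival_params()], the
#'   per-temperature fit table, regression diagnostics, excluded
#'   temperatures and (when requested) a per-parameter CI table.
#' @examples
#' d <- gen_kinetics(gen_config(seed = 1, noise_sd = 0))
#' calibrate(d, mc_iter = 0)
#' @export
calibrate <- function(dataset, endpoint = c("viability", "activity"),
                      mc_iter = 0, seed = 1L, noise_sd = NULL) {
  endpoint <- match.arg(endpoint)
  stopifnot(all(c("temperature_C", "time_s", "fraction") %in% names(dataset)))
  pt <- calibrate_point(dataset)
  params <- survival_params(pt$a, pt$T0, pt$n, endpoint = endpoint)
  fit_tbl <- purrr::map_dfr(pt$fits, function(f) {
    tibble::tibble(temperature_C = f$temperature, lambda_hat = f$lambda_hat,
                   n_hat = f$n_hat, se_lambda = f$se_lambda, se_n = f$se_n,
                   rss = f$rss, n_obs = f$n_obs)
  })
  res <- structure(
    list(params = params, fits = fit_tbl, fit_objects = pt$fits,
         regression = pt$regression, excluded = pt$excluded,
         ci = NULL, mc = NULL, data = dataset),
    class = "calibration_result")
  if (mc_iter > 0) {
    res <- monte_carlo_ci(dataset, n_iter = mc_iter, seed = seed,
                          noise_sd = noise_sd, result = res)
  }
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("<calibration_result> endpoint = %s\n", p$endpoint))
  cat(sprintf("  a  = %.4g 1/degC\n  T0 = %.4g degC\n  n  = %.4g\n",
              p$a, p$T0, p$n))
  cat(sprintf("  half-life regression R^2 = %.4f over %d temperatures",
              x$regression$r_squared, nrow(x$fits)))
  if (length(x$excluded)) {
    cat(sprintf(" (excluded: %s degC)", paste(x$excluded, collapse = ", ")))
  }
  cat("\n")
  if (!is.null(x$ci)) {
    cat("  Monte-Carlo 95% CIs:\n")
    for (i in seq_len(nrow(x$ci))) {
      cat(sprintf("    %-3s [%.4g, %.4g]\n",
                  x$ci$parameter[i], x$ci$lower[i], x$ci$upper[i]))
    }
  }
  invisible(x)
}

#' Monte-Carlo confidence intervals for calibrated parameters
#'
#' Parametric bootstrap of the two-stage calibration: every observation is
#' perturbed with independent Gaussian noise whose sd is the pooled
#' duplicate-based measurement sd, negative resamples are clamped to 0,
#' the calibration is re-run, and the 2.5/97.5 percentiles of the
#' converged iterations give the 95% intervals. Deterministic for a fixed
#' seed. Resampled fits reuse the point fit as a warm start.
#'
#' @inheritParams calibrate
#' @param n_iter Number of Monte-Carlo iterations (default 1000).
#' @param result An existing `calibration_result` for this dataset; run
#'   afresh when `NULL`.
#' @return The `calibration_result` with `ci` (tibble: parameter, lower,
#'   upper) and `mc` (iteration bookkeeping) filled in. A warning is
#'   recorded in `mc$warning` when more than 20% of iterations fail.
#' @export
monte_carlo_ci <- function(dataset, n_iter = 1000, seed = 1L,
                           noise_sd = NULL, result = NULL) {
  if (is.null(result)) {
    result <- calibrate(dataset, mc_iter = 0)
  }
  if (is.null(noise_sd)) noise_sd <- duplicate_sd(dataset)
  stopifnot(noise_sd >= 0)
  warm <- lapply(result$fit_objects, function(f) {
    c(lambda = f$lambda_hat, n = f$n_hat)
  })
  rng <- local({
    set.seed(as.integer(seed))
    function(n) stats::rnorm(n)
  })
  draws <- matrix(NA_real_, nrow = n_iter, ncol = 3,
                  dimnames = list(NULL, c("a", "T0", "n")))
  n_fail <- 0L
  base_fraction <- dataset$fraction
  for (i in seq_len(n_iter)) {
    ds <- dataset
    ds$fraction <- pmax(0, base_fraction + noise_sd * rng(length(base_fraction)))
    pt <- tryCatch(
      calibrate_point(ds, fast = TRUE, warm_starts = warm),
      error = function(e) NULL)
    if (is.null(pt)) {
      n_fail <- n_fail + 1L
    } else {
      draws[i, ] <- c(pt$a, pt$T0, pt$n)
    }
  }
  ok <- stats::complete.cases(draws)
  if (noise_sd == 0) {
    # degenerate: every resample equals the point data
    ci <- tibble::tibble(parameter = c("a", "T0", "n"),
                         lower = c(result$params$a, result$params$T0, result$params$n),
                         upper = c(result$params$a, result$params$T0, result$params$n))
  } else {
    qs <- apply(draws[ok, , drop = FALSE], 2L, stats::quantile,
                probs = c(0.025, 0.975), names = FALSE)
    ci <- tibble::tibble(parameter = c("a", "T0", "n"),
                         lower = qs[1L, ], upper = qs[2L, ])
  }
  mc <- list(n_iter = n_iter, n_failed = n_fail, seed = seed,
             noise_sd = noise_sd,
             draws = tibble::as_tibble(draws[ok, , drop = FALSE]),
             warning = if (n_fail > 0.2 * n_iter)
               sprintf("%d of %d Monte-Carlo iterations failed to converge.",
                       n_fail, n_iter) else NULL)
  if (!is.null(mc$warning)) warning(mc$warning, call. = FALSE)
  result$ci <- ci
  result$mc <- mc
  result
}

# ---- model comparison -------------------------------------------------------

gaussian_aic <- function(rss, n_obs, k) {
  # k model parameters + 1 for the residual variance
  n_obs * log(2 * pi * rss / n_obs) + n_obs + 2 * (k + 1)
}

gaussian_aicc <- function(rss, n_obs, k) {
  kk <- k + 1
  gaussian_aic(rss, n_obs, k) + 2 * kk * (kk + 1) / max(n_obs - kk - 1, 1e-9)
}

fit_first_order_curve <- function(time_s, fraction) {
  ok <- fraction > 1e-12
  m0 <- if (any(ok & time_s > 0)) {
    stats::median(-log(fraction[ok & time_s > 0]) / time_s[ok & time_s > 0])
  } else 1e-4
  fit <- minpack.lm::nlsLM(fraction ~ exp(-m * time_s),
                           start = list(m = max(m0, 1e-12)),
                           lower = c(m = 0))
  list(params = list(m = unname(stats::coef(fit)[["m"]])),
       rss = sum(stats::resid(fit)^2), k = 1L, converged = TRUE)
}

fit_geeraerd_curve <- function(time_s, fraction, N_res = 0) {
  pred <- function(m_m, Cc0) {
    grid <- sort(unique(c(0, time_s)))
    sol <- geeraerd_survival(grid, m_m = m_m, Cc0 = Cc0, N_res = N_res,
                             N0 = 1, rtol = 1e-8)
    sol$N[match(time_s, sol$time_s)]
  }
  s <- weibull_linearised_start(time_s, fraction)
  m0 <- 1 / s[["lambda"]]
  obj <- function(th) {
    p <- tryCatch(pred(exp(th[1L]), exp(th[2L])), error = function(e) NULL)
    if (is.null(p)) return(1e6)
    sum((fraction - p)^2)
  }
  opt <- stats::optim(c(log(m0), log(10)), obj, method = "Nelder-Mead",
                      control = list(maxit = 400))
  list(params = list(m_m = exp(opt$par[1L]), Cc0 = exp(opt$par[2L]),
                     N_res = N_res),
       rss = opt$value, k = 2L, converged = opt$convergence == 0)
}

fit_log_logistic_curve <- function(time_s, fraction, log_base = 10) {
  eps <- 1e-8
  lfrac <- log(pmax(fraction, eps))
  tau0 <- log(time_s[which.min(abs(fraction - 0.5))], base = log_base)
  obj <- function(th) {
    p <- log_logistic_survival(time_s, alpha_ll = th[1L], omega_ll = th[2L],
                               sigma_ll = th[3L], tau_ll = th[4L],
                               log_base = log_base)
    sum((fraction - p)^2)
  }
  opt <- stats::optim(c(0, min(lfrac), -2, tau0), obj, method = "Nelder-Mead",
                      control = list(maxit = 800))
  list(params = list(alpha_ll = opt$par[1L], omega_ll = opt$par[2L],
                     sigma_ll = opt$par[3L], tau_ll = opt$par[4L]),
       rss = opt$value, k = 4L, converged = opt$convergence == 0)
}

#' Compare mortality models on one kinetic curve
#'
#' Fits the four candidate mortality models (first-order, Weibull,
#' Geeraerd shoulder, log-logistic) to a single constant-temperature
#' curve by least squares on the fraction scale and ranks them by AIC and
#' small-sample AICc. The Geeraerd model is fitted with the shoulder ODEs
#' embedded in the objective; its residual population is fixed at 0 for
#' fraction data that decays to zero. Observations at `t = 0` are dropped
#' so that all four models (including the log-logistic, which needs
#' `log t`) are scored on the same points.
#'
#' @param data Single-temperature kinetic curve (`time_s`, `fraction`).
#' @param temperature Optional temperature label.
#' @return A tibble with one row per model: `model`, `k` (parameter
#'   count), `rss`, `aic`, `aicc`, `converged` and a `params` list-column,
#'   sorted by AIC.
#' @export
compare_models <- function(data, temperature = NULL) {
  temperature <- check_kinetic_curve(data, temperature)
  keep <- data$time_s > 0
  time_s <- data$time_s[keep]
  fraction <- data$fraction[keep]
  n_obs <- length(time_s)

  wf <- fit_weibull_kinetic(data.frame(time_s = time_s, fraction = fraction),
                            temperature = temperature)
  fits <- list(
    `first-order` = fit_first_order_curve(time_s, fraction),
    weibull = list(params = list(lambda = wf$lambda_hat, n = wf$n_hat),
                   rss = wf$rss, k = 2L, converged = TRUE),
    geeraerd = fit_geeraerd_curve(time_s, fraction),
    `log-logistic` = fit_log_logistic_curve(time_s, fraction))

  tbl <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(model = nm, k = f$k, rss = f$rss,
                   aic = gaussian_aic(f$rss, n_obs, f$k),
                   aicc = gaussian_aicc(f$rss, n_obs, f$k),
                   converged = f$converged, params = list(f$params))
  })
  dplyr::arrange(tbl, .data$aic)
}
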