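#' Gate configuration for three-channel viability cytometry
#'
#' Fixed rectangular gates on the three fluorescence channels: `FL3`
#' (chlorophyll a) separates algal cells from non-photosynthetic
#' particles; `FL2` carries the erythrosine signal of membrane-permeable
#' (dead) cells; `FL1` carries the FDA signal of enzymatically active
#' (live) cells.
#'
#' @param chl_threshold Events with `FL3` below this are non-algal.
#' @param dead_threshold Erythrosine mode: algal events with `FL2` at or
#'   above this are dead.
#' @param live_threshold FDA mode: algal events with `FL1` at or above
#'   this are live.
#' @param marker `"erythrosine"` or `"fda"`: which stain the sample
#'   carries, hence which channel classifies live vs dead.
#' @return A `gate_config` list.
#' @export
gate_config <- function(chl_threshold = 100, dead_threshold = 100,
                        live_threshold = 100,
                        marker = c("erythrosine", "fda")) {
  marker <- match.arg(marker)
  stopifnot(chl_threshold > 0, dead_threshold > 0, live_threshold > 0)
  structure(list(chl_threshold = chl_threshold,
                 dead_threshold = dead_threshold,
                 live_threshold = live_threshold, marker = marker),
            class = "gate_config")
}

#' Suggest gate thresholds from a two-component mixture
#'
#' Fits a two-component Gaussian mixture to each log-transformed channel
#' and places the threshold at the equal-density valley between the two
#' component means, giving reproducible data-driven defaults in place of
#' interactive gating.
#'
#' @param events Event table with columns `FL1`, `FL2`, `FL3`.
#' @param marker Stain carried by the sample.
#' @return A [gate_config()].
#' @export
suggest_gates <- function(events, marker = c("erythrosine", "fda")) {
  marker <- match.arg(marker)
  if (!requireNamespace("mclust", quietly = TRUE)) {
    rlang::abort("Package `mclust` is needed for mixture-based gate suggestion.")
  }
  valley <- function(x) {
    lx <- log(pmax(x, 1e-6))
    fit <- mclust::Mclust(lx, G = 2, modelNames = "V", verbose = FALSE)
    mu <- fit$parameters$mean
    sd <- sqrt(fit$parameters$variance$sigmasq)
    pr <- fit$parameters$pro
    lo <- min(mu); hi <- max(mu)
    grid <- seq(lo, hi, length.out = 512)
    d1 <- pr[1] * stats::dnorm(grid, mu[1], sd[1])
    d2 <- pr[2] * stats::dnorm(grid, mu[2], sd[2])
    exp(grid[which.min(d1 + d2)])
  }
  gate_config(chl_threshold = valley(events$FL3),
              dead_threshold = valley(events$FL2),
              live_threshold = valley(events$FL1),
              marker = marker)
}

#' Classify cytometry events as non-algal, live or dead
#'
#' Chlorophyll (`FL3`) below the chlorophyll threshold marks an event
#' non-algal. Among algal events: in erythrosine mode, high `FL2` (stain
#' uptake through a permeable membrane) marks an event dead; in FDA mode,
#' high `FL1` (enzymatic hydrolysis product) marks an event live.
#'
#' @param events Data frame with columns `FL1`, `FL2`, `FL3` (one row per
#'   event, intensities >= 0).
#' @param gates A [gate_config()].
#' @return The events tibble with an added `label` column
#'   (`"non-algal"`, `"live"`, `"dead"`).
#' @export
classify_events <- function(events, gates) {
  stopifnot(inherits(gates, "gate_config"),
            all(c("FL1", "FL2", "FL3") %in% names(events)))
  events <- tibble::as_tibble(events)
  algal <- events$FL3 >= gates$chl_threshold
  label <- rep("non-algal", nrow(events))
  if (gates$marker == "erythrosine") {
    label[algal] <- ifelse(events$FL2[algal] >= gates$dead_threshold,
                           "dead", "live")
  } else {
    label[algal] <- ifelse(events$FL1[algal] >= gates$live_threshold,
                           "live", "dead")
  }
  dplyr::mutate(events, label = label)
}

wilson_interval <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z / (1 + z^2 / n) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Viability fraction from classified events
#'
#' `live / (live + dead)` over the algal events, with a Wilson score 95%
#' confidence interval.
#'
#' @param labelled Output of [classify_events()], or any data frame with a
#'   `label` column.
#' @return A one-row tibble: `viability`, `ci_lower`, `ci_upper`,
#'   `n_live`, `n_dead`, `n_algal`, `n_events`.
#' @export
viability_fraction <- function(labelled) {
  stopifnot("label" %in% names(labelled))
  n_live <- sum(labelled$label == "live")
  n_dead <- sum(labelled$label == "dead")
  n_algal <- n_live + n_dead
  if (n_algal == 0L) {
    rlang::abort("No algal events: cannot estimate a viability fraction.",
                 class = "thermodose_estimation_error")
  }
  ci <- wilson_interval(n_live, n_algal)
  tibble::tibble(viability = n_live / n_algal,
                 ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
                 n_live = n_live, n_dead = n_dead, n_algal = n_algal,
                 n_events = nrow(labelled))
}

#' Cell-count-corrected killed fraction of a mixing series sample
#'
#' In a validation mixing series, heat-killed and fresh stocks are mixed
#' by volume, but heating degrades cells, so the killed stock is less
#' concentrated. The expected killed fraction is therefore weighted by
#' cell counts: `v C_h / (v C_h + (1 - v) C_f)` for killed-stock volume
#' fraction `v` and stock concentrations `C_h` (heated) and `C_f`
#' (fresh).
#'
#' @param volume_fraction Killed-stock volume fraction(s) in \[0, 1\].
#' @param C_heated,C_fresh Cell concentrations of the heated and fresh
#'   stocks (same units, > 0).
#' @return Corrected expected killed fraction(s).
#' @export
corrected_killed_fraction <- function(volume_fraction, C_heated, C_fresh) {
  stopifnot(all(volume_fraction >= 0 & volume_fraction <= 1),
            all(C_heated > 0), all(C_fresh > 0))
  num <- volume_fraction * C_heated
  num / (num + (1 - volume_fraction) * C_fresh)
}

#' Validation regression of measured on expected viability
#'
#' Ordinary least squares of the measured viability on the
#' cell-count-corrected expected viability across a mixing series. A
#' slope near 1 and high R-squared validate the staining/gating protocol.
#'
#' @param mix Data frame with columns `volume_fraction` (of killed
#'   stock), `C_heated`, `C_fresh`, `measured_viability`.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
validation_regression <- function(mix) {
  need <- c("volume_fraction", "C_heated", "C_fresh", "measured_viability")
  stopifnot(all(need %in% names(mix)))
  if (nrow(mix) < 3L) {
    rlang::abort("Need at least 3 mixing-series samples for the validation regression.",
                 class = "thermodose_domain_error")
  }
  expected <- 1 - corrected_killed_fraction(mix$volume_fraction,
                                            mix$C_heated, mix$C_fresh)
  fit <- stats::lm(mix$measured_viability ~ expected)
  sm <- suppressWarnings(summary(fit))
  r2 <- if (stats::var(mix$measured_viability) == 0) 0 else sm$r.squared
  tibble::tibble(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n = nrow(mix))
}
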