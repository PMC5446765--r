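read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("%s file not found: %s", what, path),
                 class = "thermodose_parse_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    rlang::abort(sprintf("%s file %s is missing column(s): %s",
                         what, path, paste(missing, collapse = ", ")),
                 class = "thermodose_parse_error")
  }
  x
}

#' Read and write the pipeline's CSV and JSON dialects
#'
#' Kinetics: `temperature_C,time_s,replicate,fraction[,endpoint,marker,assay_delay_h]`.
#' Rapid light curves: `sample_id,irradiance,F,FM_prime`.
#' Cytometry events: `FL1,FL2,FL3`.
#' Climate: `time_s,temp_C,irradiance_umol_m2_s` (the shorter `irradiance`
#' is accepted on read). Parameter sets are JSON
#' `{endpoint, a, T0, n}`.
#'
#' @param path File path.
#' @return A tibble (readers) or the path invisibly (writers).
#' @name io
NULL

#' @rdname io
#' @export
read_kinetics <- function(path) {
  read_csv_checked(path, c("temperature_C", "time_s", "replicate", "fraction"),
                   "Kinetics")
}

#' @rdname io
#' @export
read_rlc <- function(path) {
  read_csv_checked(path, c("sample_id", "irradiance", "F", "FM_prime"),
                   "Rapid-light-curve")
}

#' @rdname io
#' @export
read_events <- function(path) {
  read_csv_checked(path, c("FL1", "FL2", "FL3"), "Cytometry event")
}

#' @rdname io
#' @export
read_climate <- function(path) {
  x <- read_csv_checked(path, c("time_s", "temp_C"), "Climate")
  if ("irradiance_umol_m2_s" %in% names(x)) {
    x <- dplyr::rename(x, irradiance = "irradiance_umol_m2_s")
  }
  x
}

#' @rdname io
#' @param x Object to write.
#' @export
write_climate <- function(x, path) {
  out <- dplyr::rename(x, irradiance_umol_m2_s = "irradiance")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname io
#' @export
read_gates_yaml <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Gates file not found: %s", path),
                 class = "thermodose_parse_error")
  }
  g <- yaml::read_yaml(path)
  gate_config(chl_threshold = g$chl_threshold %||% 100,
              dead_threshold = g$dead_threshold %||% 100,
              live_threshold = g$live_threshold %||% 100,
              marker = g$marker %||% "erythrosine")
}

#' @rdname io
#' @export
write_gates_yaml <- function(x, path) {
  stopifnot(inherits(x, "gate_config"))
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname io
#' @export
read_params_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  survival_params(p$a, p$T0, p$n, endpoint = p$endpoint %||% "viability")
}

#' @rdname io
#' @export
write_params_json <- function(x, path) {
  x <- as_survival_params(x)
  jsonlite::write_json(list(endpoint = x$endpoint, a = x$a, T0 = x$T0, n = x$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Calibration pipeline: kinetics CSV in, parameter files out
#'
#' Reads a kinetics CSV, runs the two-stage calibration (optionally with
#' Monte-Carlo confidence intervals and the four-model comparison), and
#' writes a parameter JSON, a per-temperature fit report CSV and the
#' half-life regression points.
#'
#' @param kinetics_csv Input kinetics file.
#' @param out_dir Output directory (created if absent).
#' @param endpoint Endpoint label.
#' @param mc_iter Monte-Carlo iterations (0 = point estimates only).
#' @param seed Seed for the Monte-Carlo stage.
#' @param model_comparison Also write a per-temperature AIC comparison
#'   table.
#' @return The `calibration_result`, invisibly.
#' @export
pipeline_calibrate <- function(kinetics_csv, out_dir = ".",
                               endpoint = "viability",
                               mc_iter = 0, seed = 1L,
                               model_comparison = FALSE) {
  dat <- read_kinetics(kinetics_csv)
  res <- calibrate(dat, endpoint = endpoint, mc_iter = mc_iter, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(endpoint = res$params$endpoint,
              a = res$params$a, T0 = res$params$T0, n = res$params$n,
              r_squared = res$regression$r_squared,
              excluded_temperatures = res$excluded)
  if (!is.null(res$ci)) {
    out$ci95 <- stats::setNames(
      purrr::map2(res$ci$lower, res$ci$upper, c), res$ci$parameter)
  }
  jsonlite::write_json(out, file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(res$fits, file.path(out_dir, "fits_by_temperature.csv"))
  if (model_comparison) {
    cmp <- purrr::map_dfr(res$fit_objects, function(f) {
      sub <- dat[dat$temperature_C == f$temperature, ]
      dplyr::mutate(dplyr::select(compare_models(sub, f$temperature), -"params"),
                    temperature_C = f$temperature, .before = 1L)
    })
    readr::write_csv(cmp, file.path(out_dir, "model_comparison.csv"))
  }
  invisible(res)
}

#' Simulation pipeline: climate CSV in, collapse summary out
#'
#' @param climate_csv Input climate file.
#' @param out_dir Output directory.
#' @param config A [sim_config()].
#' @param growth A [growth_model()].
#' @return The `sim_result`, invisibly; writes `daily.csv` and
#'   `summary.json`.
#' @export
pipeline_simulate <- function(climate_csv, out_dir = ".",
                              config = sim_config(),
                              growth = growth_model()) {
  clim <- read_climate(climate_csv)
  res <- run_simulation(clim, config = config, growth = growth)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(res$daily, file.path(out_dir, "daily.csv"))
  jsonlite::write_json(as.list(res$summary), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Rapid-light-curve batch pipeline
#'
#' Fits every sample in an RLC file; samples whose fit fails are skipped
#' with a warning and the batch continues.
#'
#' @param rlc_csv Input file (`sample_id,irradiance,F,FM_prime`).
#' @param out_csv Optional output path for the per-sample parameter
#'   table.
#' @return Tibble of per-sample Eilers-Peeters parameters.
#' @export
pipeline_rlc <- function(rlc_csv, out_csv = NULL) {
  dat <- read_rlc(rlc_csv)
  out <- purrr::map_dfr(split(dat, dat$sample_id), function(sub) {
    fit <- tryCatch(fit_eilers_peeters(sub), error = function(e) {
      warning(sprintf("sample %s skipped: %s", sub$sample_id[1L],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(fit)) return(NULL)
    dplyr::mutate(glance(fit), sample_id = sub$sample_id[1L], .before = 1L)
  })
  if (!is.null(out_csv)) readr::write_csv(out, out_csv)
  out
}

#' Cytometry gating batch pipeline
#'
#' @param events_csvs Character vector of event-table files.
#' @param gates A [gate_config()].
#' @param out_csv Optional output path.
#' @return Tibble of per-file viability fractions with Wilson intervals.
#' @export
pipeline_gate <- function(events_csvs, gates = gate_config(),
                          out_csv = NULL) {
  out <- purrr::map_dfr(events_csvs, function(path) {
    res <- tryCatch(
      viability_fraction(classify_events(read_events(path), gates)),
      error = function(e) {
        warning(sprintf("%s skipped: %s", path, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(res)) return(NULL)
    dplyr::mutate(res, file = path, .before = 1L)
  })
  if (!is.null(out_csv)) readr::write_csv(out, out_csv)
  out
}

#' Write synthetic inputs in the pipeline's CSV dialects
#'
#' @param what One of `"kinetics"`, `"rlc"`, `"cytometry"`, `"climate"`.
#' @param path Output CSV path.
#' @param config A [gen_config()].
#' @param ... Passed to the underlying generator (e.g. `viability`,
#'   `n_events` for cytometry; `n` for RLC).
#' @return The path, invisibly.
#' @export
write_synthetic_inputs <- function(what = c("kinetics", "rlc", "cytometry",
                                            "climate"),
                                   path, config = gen_config(), ...) {
  what <- match.arg(what)
  x <- switch(what,
              kinetics = gen_kinetics(config),
              rlc = gen_rlc(config, ...),
              cytometry = gen_cytometry(config = config, ...),
              climate = gen_climate(config))
  if (what == "climate") write_climate(x, path) else readr::write_csv(x, path)
  invisible(path)
}
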