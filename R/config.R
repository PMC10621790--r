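#' Clinical-trial model configuration
#'
#' Bundles the five clinical-trial model components (mechanistic typical
#' parameters inside the population model, demographics, inter-occasion,
#' execution and measurement layers) together with trial-level settings into
#' one object that every protocol runner consumes.
#'
#' @param population A [population_parameters()] object.
#' @param demo A [demographics()] object.
#' @param iov An [iov_config()].
#' @param execution An [execution_config()].
#' @param measurement A [measurement_config()].
#' @param y_star Target INR of dose individualisation (default 2.5).
#' @param range_low,range_high Therapeutic INR range bounds (default 2, 3).
#' @param dose_step Dose rounding granularity in mg (default 0.5).
#' @param dose_max Maximum daily dose in mg (default 30).
#' @param report_actual_times If `TRUE`, datasets record actual (delayed)
#'   times instead of the nominal schedule. Default `FALSE`, mirroring the
#'   common practice of reporting nominal schedules.
#' @return A `ct_config` object.
#' @export
ct_config <- function(population = population_parameters(),
                      demo = demographics(),
                      iov = iov_config(),
                      execution = execution_config(),
                      measurement = measurement_config(),
                      y_star = 2.5, range_low = 2, range_high = 3,
                      dose_step = 0.5, dose_max = 30,
                      report_actual_times = FALSE) {
  stopifnot(range_low < y_star, y_star < range_high, dose_step > 0,
            dose_max > 0)
  structure(list(population = population, demo = demo, iov = iov,
                 execution = execution, measurement = measurement,
                 y_star = y_star, range_low = range_low,
                 range_high = range_high, dose_step = dose_step,
                 dose_max = dose_max,
                 report_actual_times = report_actual_times),
            class = "ct_config")
}

#' Round a dose to the trial granularity and cap it
#'
#' Doses are rounded to the nearest `dose_step` (tablet-like granularity) and
#' capped at `dose_max`.
#'
#' @param dose_mg Numeric dose(s) in mg.
#' @param config A [ct_config()] (only `dose_step`/`dose_max` are used).
#' @return Rounded, capped dose(s).
#' @export
round_dose <- function(dose_mg, config = ct_config()) {
  pmin(config$dose_max, pmax(0, round(dose_mg / config$dose_step) *
                                  config$dose_step))
}

#' Write / read a trial configuration as JSON
#'
#' @param config A [ct_config()].
#' @param path File path (`.json`).
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   [ct_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ct_config"))
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (!is.null(names(x))) as.list(x) # keep names as JSON keys
    else x
  }
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ct_config(
    population = population_parameters(
      typical = do.call(individual_parameters, as.list(x$population$typical)),
      cyp2c9_ke_mult = unlist(x$population$cyp2c9_ke_mult),
      vkorc1_ec50_mult = unlist(x$population$vkorc1_ec50_mult),
      age_slope = x$population$age_slope,
      omegas = unlist(x$population$omegas)),
    demo = demographics(cyp2c9_freqs = unlist(x$demo$cyp2c9_freqs),
                        vkorc1_freqs = unlist(x$demo$vkorc1_freqs),
                        age_mean = x$demo$age_mean, age_sd = x$demo$age_sd,
                        age_range = unlist(x$demo$age_range)),
    iov = iov_config(x$iov$mu_eta, x$iov$sigma_eta),
    execution = execution_config(x$execution$tau_min),
    measurement = measurement_config(x$measurement$sigma,
                                     lloq = x$measurement$lloq),
    y_star = x$y_star, range_low = x$range_low, range_high = x$range_high,
    dose_step = x$dose_step, dose_max = x$dose_max,
    report_actual_times = isTRUE(x$report_actual_times))
}

config_hash <- function(config) rlang::hash(unclass(config))
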