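#' Inter-occasion variability configuration
#'
#' Daily multipliers on the vitamin K input rate are drawn from
#' `Normal(mu_eta, sigma_eta^2)`, one independent draw per simulation day, and
#' truncated below at 0.05 so that the input rate stays positive.
#'
#' @param mu_eta Mean multiplier (default 1).
#' @param sigma_eta SD of the multiplier (default 0.1, i.e. the input rate
#'   varies by about 10\% from day to day).
#' @return An `iov_config` object.
#' @export
iov_config <- function(mu_eta = 1, sigma_eta = 0.1) {
  stopifnot(mu_eta > 0, sigma_eta >= 0)
  structure(list(mu_eta = mu_eta, sigma_eta = sigma_eta), class = "iov_config")
}

#' Execution-variability configuration
#'
#' Actual administration and monitoring times deviate from the nominal
#' schedule by exponentially distributed delays with mean `tau_min` minutes.
#'
#' @param tau_min Mean delay in minutes (default 30).
#' @return An `execution_config` object.
#' @export
execution_config <- function(tau_min = 30) {
  stopifnot(tau_min >= 0)
  structure(list(tau_min = tau_min), class = "execution_config")
}

#' Measurement-noise configuration
#'
#' Measurements are lognormal around the noise-free model output: the model
#' value is the median and `sigma` the log-scale SD, giving errors of roughly
#' `100 * sigma` percent of the model output.
#'
#' @param sigma Lognormal scale (default 0.1).
#' @param lloq Optional lower limit of quantification; measurements below it
#'   are reported at `lloq`.
#' @return A `measurement_config` object.
#' @export
measurement_config <- function(sigma = 0.1, lloq = NULL) {
  stopifnot(sigma >= 0)
  structure(list(sigma = sigma, lloq = lloq), class = "measurement_config")
}

#' Sample daily occasion multipliers
#'
#' One independent `Normal(mu_eta, sigma_eta^2)` draw per day, truncated below
#' at 0.05.
#'
#' @param n_days Number of days (>= 1).
#' @param cfg An [iov_config()].
#' @param seed Optional integer seed.
#' @return An [occasion_series()].
#' @export
#' @examples
#' sample_occasions(3, iov_config(sigma_eta = 0), seed = 1)$eta_by_day
sample_occasions <- function(n_days, cfg = iov_config(), seed = NULL) {
  stopifnot(n_days >= 1, inherits(cfg, "iov_config"))
  with_seed(seed, {
    eta <- stats::rnorm(n_days, cfg$mu_eta, cfg$sigma_eta)
    occasion_series(pmax(eta, 0.05))
  })
}

#' Perturb a nominal schedule with execution delays
#'
#' Each nominal administration time and each nominal monitoring time receives
#' an independent exponential delay with mean `tau_min` minutes. When a dose
#' and a measurement share a nominal time, a single delay is drawn and applied
#' to both events. Dose amounts are unchanged (the execution layer perturbs
#' times only).
#'
#' @param nominal A nominal [dosing_regimen()].
#' @param nominal_measurement_times Numeric vector of nominal monitoring
#'   times (h), sorted.
#' @param cfg An [execution_config()].
#' @param seed Optional integer seed.
#' @return List with `regimen` (actual [dosing_regimen()]) and
#'   `measurement_times` (actual times, h).
#' @export
perturb_schedule <- function(nominal, nominal_measurement_times,
                             cfg = execution_config(), seed = NULL) {
  stopifnot(inherits(nominal, "dosing_regimen"),
            inherits(cfg, "execution_config"))
  if (is.unsorted(nominal_measurement_times))
    stop("nominal measurement times must be sorted", call. = FALSE)
  with_seed(seed, {
    tau_h <- cfg$tau_min / 60
    draw <- function(n) if (tau_h == 0) rep(0, n) else stats::rexp(n, rate = 1 / tau_h)
    dose_delay <- draw(length(nominal$time_h))
    meas_delay <- draw(length(nominal_measurement_times))
    # coincident nominal dose/measurement -> one shared delay for both events
    shared <- match(nominal_measurement_times, nominal$time_h)
    hit <- !is.na(shared)
    meas_delay[hit] <- dose_delay[shared[hit]]
    list(regimen = dosing_regimen(nominal$dose_mg,
                                  nominal$time_h + dose_delay,
                                  kind = "actual"),
         measurement_times = nominal_measurement_times + meas_delay)
  })
}

#' Sample a noisy measurement around the model output
#'
#' Lognormal with median `y_bar` and log-scale `sigma`.
#'
#' @param y_bar Noise-free model output (> 0).
#' @param cfg A [measurement_config()].
#' @param seed Optional integer seed.
#' @return Measured value(s), same length as `y_bar`.
#' @export
sample_measurement <- function(y_bar, cfg = measurement_config(), seed = NULL) {
  stopifnot(inherits(cfg, "measurement_config"))
  if (any(y_bar <= 0))
    stop("y_bar must be > 0 (lognormal median undefined otherwise)",
         call. = FALSE)
  with_seed(seed, {
    y <- stats::rlnorm(length(y_bar), meanlog = log(y_bar), sdlog = cfg$sigma)
    if (!is.null(cfg$lloq)) y <- pmax(y, cfg$lloq)
    y
  })
}
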