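#' Simulate warfarin concentration and INR for one individual
#'
#' Solves the reduced warfarin PKPD model for a parameterised individual under
#' an arbitrary dosing regimen. Pharmacokinetics are a one-compartment model
#' with first-order absorption (`da_d/dt = -ka a_d + r(t)`,
#' `da_c/dt = ka a_d - ke a_c`); dose events are instantaneous bolus additions
#' to the dose compartment. The central concentration `C = a_c/V` inhibits,
#' via a Hill function `E(C) = 1 - C^gamma/(EC50^gamma + C^gamma)`, the
#' production input of a transit chain of clotting activity
#' (`dA1/dt = ktr (eta_day E(C) - A1)`, `dAi/dt = ktr (A_{i-1} - A_i)`,
#' `ktr = n_transit/MTT`), and the INR readout is
#' `inr_base + inr_max * max(0, 1 - A_n)^lam`. The daily occasion multiplier
#' `eta` scales the production input (the vitamin K input analogue) and is
#' piecewise constant over calendar days.
#'
#' @param regimen A [dosing_regimen()].
#' @param psi An [individual_parameters()] object.
#' @param times Sorted numeric time grid (h) on which to report the solution.
#' @param occasions Optional [occasion_series()]; absent means all `eta = 1`.
#' @param rtol,atol Solver tolerances of the adaptive Dormand-Prince 5(4)
#'   stepper. Defaults are strict enough that the concentration agrees with
#'   the closed-form single-dose solution to better than 1e-6 relative.
#' @param backend Optional dynamics backend (see
#'   [register_dynamics_backend()]); `NULL` uses the built-in reduced model.
#'
#' @return A `response_trajectory`: list with `times_h`, `conc_mg_per_L`
#'   (central warfarin concentration, mg/L) and `inr` (noise-free INR), all of
#'   the same length as `times`.
#' @export
#' @examples
#' psi <- individual_parameters()
#' tr <- simulate_response(dosing_regimen(10, 0), psi, times = c(10, 35, 60))
#' tr$conc_mg_per_L
simulate_response <- function(regimen, psi, times, occasions = NULL,
                              rtol = 1e-8, atol = 1e-10, backend = NULL) {
  stopifnot(inherits(regimen, "dosing_regimen"),
            inherits(psi, "individual_parameters"))
  if (length(times) == 0) stop("empty time grid", call. = FALSE)
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  eta <- if (is.null(occasions)) 1 else occasions$eta_by_day
  if (!is.null(backend)) {
    fn <- resolve_dynamics_backend(backend)
    return(fn(regimen, psi, times, eta))
  }
  out <- wf_simulate_cpp(psi_vector(psi), regimen$dose_mg, regimen$time_h,
                         eta, as.numeric(times), rtol, atol)
  structure(list(times_h = as.numeric(times), conc_mg_per_L = out[, 1],
                 inr = out[, 2]),
            class = "response_trajectory")
}

#' Approximate steady-state INR under constant daily dosing
#'
#' Simulates at least 30 days of once-daily dosing and returns the trough INR
#' (just before the next scheduled dose) on the final simulated day. This is
#' an approximate steady state: warfarin's elimination half-life and the
#' transit-chain delay make true equilibration asymptotic.
#'
#' @param daily_dose_mg Daily dose (mg), >= 0.
#' @param psi An [individual_parameters()] object.
#' @param n_days Number of simulated dosing days (>= 30).
#' @return Trough INR on the final day (dimensionless).
#' @export
#' @examples
#' steady_state_inr(0, individual_parameters()) # == inr_base
steady_state_inr <- function(daily_dose_mg, psi, n_days = 35) {
  stopifnot(daily_dose_mg >= 0, n_days >= 30)
  if (daily_dose_mg == 0) return(psi$inr_base)
  reg <- dosing_regimen(rep(daily_dose_mg, n_days), 24 * (seq_len(n_days) - 1))
  tr <- simulate_response(reg, psi, times = 24 * n_days)
  tr$inr[length(tr$inr)]
}

#' Calibrate the typical EC50 against a reference maintenance dose
#'
#' One-dimensional calibration pinning the default typical patient's response:
#' EC50 is chosen so that the approximate steady-state INR under a constant
#' reference daily dose equals the target INR. The package default EC50
#' (6.4204 mg/L) was produced by this routine with a 5 mg/day reference and a
#' 2.5 INR target for the reference (GG, *1*1, age 71) patient; see the
#' methods vignette.
#'
#' @param psi Template [individual_parameters()]; its EC50 entry is replaced.
#' @param reference_dose_mg Reference daily dose (mg).
#' @param target_inr Target steady-state INR.
#' @param interval Search interval for EC50 (mg/L).
#' @return The calibrated EC50 (mg/L).
#' @export
calibrate_ec50 <- function(psi = individual_parameters(),
                           reference_dose_mg = 5, target_inr = 2.5,
                           interval = c(0.1, 100)) {
  f <- function(ec50) {
    p <- psi
    p$EC50 <- ec50
    steady_state_inr(reference_dose_mg, p) - target_inr
  }
  stats::uniroot(f, interval, tol = 1e-6)$root
}

# --- pluggable dynamics backends (e.g. an externally supplied mechanistic
# model honouring the simulate_response contract) --------------------------

the_backends <- new.env(parent = emptyenv())

#' Register an alternative dynamics backend
#'
#' Hook for plugging in an external mechanistic model (for instance a full
#' coagulation-network model exported from an SBML description and simulated
#' elsewhere) while keeping the [simulate_response()] contract. The backend is
#' a function `(regimen, psi, times, eta)` returning a list with `times_h`,
#' `conc_mg_per_L` and `inr`. No SBML parser ships with this package; the hook
#' accepts any R-level simulator. Disabled unless explicitly selected through
#' the `backend` argument of [simulate_response()].
#'
#' @param name Backend name.
#' @param fn Simulator function `(regimen, psi, times, eta)`.
#' @return `name`, invisibly.
#' @export
register_dynamics_backend <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = the_backends)
  invisible(name)
}

resolve_dynamics_backend <- function(backend) {
  if (is.function(backend)) return(backend)
  if (is.character(backend) && exists(backend, envir = the_backends))
    return(get(backend, envir = the_backends))
  stop(sprintf("unknown dynamics backend '%s'", backend), call. = FALSE)
}

# fresh ODE state at drug-free baseline for stateful trial loops
wf_initial_state <- function(psi) c(0, 0, rep(1, psi$n_transit))
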