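#' Linear dose-adjustment heuristic
#'
#' Emulates a physician adjusting the warfarin dose under an assumed linear
#' INR-dose relationship: the next dose is `d_prev * y_star / y_j`, rounded to
#' the trial dose granularity and capped at the maximum daily dose.
#'
#' @param d_prev Previously administered dose (mg, >= 0).
#' @param y_star Target INR (> 0).
#' @param y_j INR measured just before the adjusted administration (> 0).
#' @param config A [ct_config()] supplying rounding granularity and cap.
#' @return Adjusted dose (mg).
#' @export
#' @examples
#' heuristic_dose(7.5, 2.5, 1.5) # 12.5
heuristic_dose <- function(d_prev, y_star, y_j, config = ct_config()) {
  stopifnot(d_prev >= 0, y_star > 0)
  if (y_j <= 0) stop("measured INR must be > 0", call. = FALSE)
  round_dose(d_prev * y_star / y_j, config)
}

#' Safety-stop rule
#'
#' A trial arm is discontinued for a patient once three consecutive INR
#' measurements all exceed 5.
#'
#' @param inr_history Ordered numeric vector of INR measurements.
#' @return `TRUE` iff any three consecutive entries all exceed 5.
#' @export
#' @examples
#' safety_stop(c(5.1, 5.2, 5.3)) # TRUE
#' safety_stop(c(5.1, 4.9, 5.2, 5.3)) # FALSE
safety_stop <- function(inr_history) {
  n <- length(inr_history)
  if (n < 3) return(FALSE)
  above <- inr_history > 5
  any(above[1:(n - 2)] & above[2:(n - 1)] & above[3:n])
}

#' Monitoring record of one patient
#'
#' The data a dosing agent may see: the measurements taken so far and the
#' regimen administered so far. Contains no mechanistic parameters -- agents
#' are separated from the virtual patient's truth by construction.
#'
#' @param measurements Tibble with `time_h`, `value` (strictly increasing
#'   times).
#' @param regimen_so_far A [dosing_regimen()] of administered doses.
#' @param patient_id Optional identifier (used by stateful agents to key
#'   warm starts).
#' @return A `monitoring_record` object.
#' @export
monitoring_record <- function(measurements = tibble::tibble(time_h = numeric(),
                                                            value = numeric()),
                              regimen_so_far = dosing_regimen(),
                              patient_id = NA_integer_) {
  measurements <- tibble::as_tibble(measurements)
  if (nrow(measurements) > 1 && any(diff(measurements$time_h) <= 0))
    stop("measurement times must be strictly increasing", call. = FALSE)
  structure(list(measurements = measurements, regimen_so_far = regimen_so_far,
                 patient_id = patient_id),
            class = "monitoring_record")
}

#' Construct a dosing agent
#'
#' The common interface every MIPD method implements: given the patient's
#' covariates, the monitoring record, the target INR and the 0-based day
#' index, return the next daily dose in mg. Agents are stateless between
#' patients.
#'
#' @param name Agent name (used in error messages and metadata).
#' @param next_dose Function `(chi, record, y_star, day)` returning a dose.
#' @param reset Optional function called before each new patient.
#' @return A `dosing_agent` object.
#' @export
dosing_agent <- function(name, next_dose, reset = NULL) {
  stopifnot(is.function(next_dose))
  structure(list(name = name, next_dose = next_dose, reset = reset),
            class = "dosing_agent")
}

#' Stub agent administering no drug
#'
#' @return A [dosing_agent()] that always returns 0 mg.
#' @export
zero_dose_agent <- function() {
  dosing_agent("zero-dose stub", function(chi, record, y_star, day) 0)
}

# --- generic day-by-day engine --------------------------------------------

# Simulates one patient through a daily-dosing protocol with all stochastic
# layers: IOV on the vitamin K input, shared execution delays for coincident
# dose/measurement events, and lognormal measurement noise. Pre-dose
# measurements share the day's delay with the dose. decide_dose(day, history)
# sees only measured INRs and past doses (information barrier).
run_daily_protocol <- function(psi, n_days, measurement_days, config,
                               decide_dose, stop_rule = TRUE) {
  occ <- sample_occasions(n_days + 1, config$iov)
  nominal_dose_t <- 24 * (seq_len(n_days) - 1)
  nominal_meas_t <- 24 * measurement_days
  sched <- perturb_schedule(dosing_regimen(rep(0, n_days), nominal_dose_t),
                            nominal_meas_t, config$execution)
  dose_actual_t <- sched$regimen$time_h
  meas_actual_t <- sched$measurement_times

  state <- wf_initial_state(psi)
  psi_v <- psi_vector(psi)
  t_cur <- 0
  doses <- numeric(0)
  meas_val <- numeric(0)
  meas_day <- integer(0)
  stopped <- FALSE
  no_dose <- numeric(0)
  for (day in 0:(n_days - 1)) {
    mi <- match(day, measurement_days)
    if (!is.na(mi)) {
      t_ev <- max(meas_actual_t[mi], t_cur)
      state <- wf_step_cpp(state, psi_v, t_cur, t_ev, no_dose, no_dose,
                           occ$eta_by_day, 1e-8, 1e-10)
      t_cur <- t_ev
      y <- sample_measurement(wf_inr_cpp(state, psi_v), config$measurement)
      meas_val <- c(meas_val, y)
      meas_day <- c(meas_day, day)
      if (stop_rule && safety_stop(meas_val)) {
        stopped <- TRUE
        break
      }
    }
    d <- decide_dose(day, meas_val, doses)
    t_ev <- max(dose_actual_t[day + 1], t_cur)
    state <- wf_step_cpp(state, psi_v, t_cur, t_ev, no_dose, no_dose,
                         occ$eta_by_day, 1e-8, 1e-10)
    t_cur <- t_ev
    state[1] <- state[1] + d
    doses <- c(doses, d)
  }
  # trailing measurements after the last dose day (e.g. an end-of-trial
  # reading scheduled on a day with no further dosing)
  if (!stopped) {
    trailing <- which(measurement_days > n_days - 1)
    for (mi in trailing) {
      t_ev <- max(meas_actual_t[mi], t_cur)
      state <- wf_step_cpp(state, psi_v, t_cur, t_ev, no_dose, no_dose,
                           occ$eta_by_day, 1e-8, 1e-10)
      t_cur <- t_ev
      y <- sample_measurement(wf_inr_cpp(state, psi_v), config$measurement)
      meas_val <- c(meas_val, y)
      meas_day <- c(meas_day, measurement_days[mi])
      if (stop_rule && safety_stop(meas_val)) {
        stopped <- TRUE
        break
      }
    }
  }
  rep_t <- if (config$report_actual_times) {
    list(meas = meas_actual_t[match(meas_day, measurement_days)],
         dose = dose_actual_t[seq_along(doses)])
  } else {
    list(meas = 24 * meas_day, dose = nominal_dose_t[seq_along(doses)])
  }
  list(measurement_day = meas_day, measurement_time = rep_t$meas,
       inr = meas_val, doses = doses, dose_time = rep_t$dose,
       stopped = stopped)
}

# dose decision shared by phases II and III: fixed induction doses, then the
# linear heuristic on adjustment days, repeating the last dose in between
phase_heuristic_decider <- function(adjust_days, config) {
  induction <- c(10, 7.5, 5)
  function(day, meas_so_far, doses_so_far) {
    if (day < 3) return(induction[day + 1])
    if (day %in% adjust_days)
      heuristic_dose(doses_so_far[length(doses_so_far)], config$y_star,
                     meas_so_far[length(meas_so_far)], config)
    else doses_so_far[length(doses_so_far)]
  }
}

#' Simulate the phase I trial (single-dose pharmacokinetics)
#'
#' 60 individuals each receive a single 10 mg dose; the blood warfarin
#' concentration is measured at nominal 10, 35 and 60 h after administration.
#' All stochastic layers apply; the dataset records the nominal schedule
#' unless `report_actual_times` is set.
#'
#' @param config A [ct_config()].
#' @param n Cohort size (default 60).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @return A [trial_dataset()] with concentration rows.
#' @export
run_phase1 <- function(config = ct_config(), n = 60, seed = 1) {
  set.seed(seed)
  cohort <- sample_cohort(config$population, config$demo, n)
  nominal_t <- c(10, 35, 60)
  meas <- vector("list", n)
  for (i in seq_len(n)) {
    psi <- cohort$parameters[[i]]
    sched <- perturb_schedule(dosing_regimen(10, 0), nominal_t,
                              config$execution)
    occ <- sample_occasions(4, config$iov)
    tr <- simulate_response(sched$regimen, psi,
                            times = sort(sched$measurement_times),
                            occasions = occ)
    conc <- tr$conc_mg_per_L[rank(sched$measurement_times)]
    y <- sample_measurement(conc, config$measurement)
    rep_t <- if (config$report_actual_times) sched$measurement_times else nominal_t
    meas[[i]] <- tibble::tibble(patient_id = i,
                                observable = "warfarin_conc_mg_per_L",
                                time_h = rep_t, value = y)
  }
  doses <- tibble::tibble(patient_id = seq_len(n), time_h = 0, dose_mg = 10)
  trial_dataset(do.call(rbind, meas), doses, cohort$covariates,
                metadata = list(trial = "phase1", seed = seed,
                                config_hash = config_hash(config),
                                stopped = integer(0)))
}

#' Simulate the phase II trial (induction and heuristic dose adjustment)
#'
#' 100 individuals are dosed daily for 3 weeks. The first three doses are
#' fixed (10, 7.5, 5 mg); the 4th dose (day 3) and the doses on days 5, 7 and
#' 13 are set by the linear heuristic from the INR taken just before that
#' administration; between adjustments the last dose repeats. The INR is
#' measured on days 0, 1, 2, 3 (induction) and 5, 7, 13, 20, pre-dose. A
#' patient's arm is discontinued after three consecutive INR measurements
#' above 5.
#'
#' @inheritParams run_phase1
#' @param n Cohort size (default 100).
#' @param n_days Trial duration in days (default 21).
#' @return A [trial_dataset()] with INR rows.
#' @export
run_phase2 <- function(config = ct_config(), n = 100, seed = 1, n_days = 21) {
  set.seed(seed)
  cohort <- sample_cohort(config$population, config$demo, n)
  meas_days <- c(0, 1, 2, 3, 5, 7, 13, 20)
  decide <- phase_heuristic_decider(c(3, 5, 7, 13), config)
  meas <- list(); doses <- list(); stopped <- integer(0)
  for (i in seq_len(n)) {
    res <- run_daily_protocol(cohort$parameters[[i]], n_days, meas_days,
                              config, decide, stop_rule = TRUE)
    meas[[i]] <- tibble::tibble(patient_id = i, observable = "INR",
                                time_h = res$measurement_time, value = res$inr)
    doses[[i]] <- tibble::tibble(patient_id = i, time_h = res$dose_time,
                                 dose_mg = res$doses)
    if (res$stopped) stopped <- c(stopped, i)
  }
  trial_dataset(do.call(rbind, meas), do.call(rbind, doses),
                cohort$covariates,
                metadata = list(trial = "phase2", seed = seed,
                                config_hash = config_hash(config),
                                stopped = stopped))
}

#' Simulate the phase III trial (maintenance-dose equilibration)
#'
#' The phase II design extended to 1000 individuals and 8 weeks: additional
#' heuristic adjustments on days 27 and 34, then a constant dose for the final
#' 3 weeks so that patients equilibrate to maintenance treatment. The reported
#' dataset holds, per surviving patient, one INR row measured at the end of
#' the trial (day 55) and the final (maintenance) dose.
#'
#' @inheritParams run_phase1
#' @param n Cohort size (default 1000).
#' @return A [trial_dataset()] with one INR row and one dose row per
#'   surviving patient.
#' @export
run_phase3 <- function(config = ct_config(), n = 1000, seed = 1) {
  set.seed(seed)
  cohort <- sample_cohort(config$population, config$demo, n)
  n_days <- 56
  meas_days <- c(0, 1, 2, 3, 5, 7, 13, 20, 27, 34, 55)
  decide <- phase_heuristic_decider(c(3, 5, 7, 13, 27, 34), config)
  meas <- list(); doses <- list(); stopped <- integer(0)
  for (i in seq_len(n)) {
    res <- run_daily_protocol(cohort$parameters[[i]], n_days, meas_days,
                              config, decide, stop_rule = TRUE)
    if (res$stopped) {
      stopped <- c(stopped, i)
      meas[[i]] <- tibble::tibble(patient_id = i, observable = "INR",
                                  time_h = res$measurement_time,
                                  value = res$inr)
      doses[[i]] <- tibble::tibble(patient_id = i, time_h = res$dose_time,
                                   dose_mg = res$doses)
    } else {
      k <- length(res$inr)
      meas[[i]] <- tibble::tibble(patient_id = i, observable = "INR",
                                  time_h = res$measurement_time[k],
                                  value = res$inr[k])
      m <- length(res$doses)
      doses[[i]] <- tibble::tibble(patient_id = i, time_h = res$dose_time[m],
                                   dose_mg = res$doses[m])
    }
  }
  trial_dataset(do.call(rbind, meas), do.call(rbind, doses),
                cohort$covariates,
                metadata = list(trial = "phase3", seed = seed,
                                config_hash = config_hash(config),
                                stopped = stopped))
}

#' Simulate an MIPD trial
#'
#' Every patient is treated with daily warfarin doses for `n_days` days. Each
#' day the INR is measured before the dose administration (all stochastic
#' layers applied, shared execution delay for the coincident measurement and
#' dose), the monitoring record and covariates are passed to the dosing
#' agent, and the returned dose is administered. No safety-stop rule is
#' applied, exposing agent weaknesses fully. The record passed to the agent
#' holds nominal times unless `report_actual_times` is set.
#'
#' @param config A [ct_config()].
#' @param agent A [dosing_agent()].
#' @param cohort A cohort from [sample_cohort()], or `NULL` to draw `n`
#'   patients from the configured demographics.
#' @param n Cohort size when `cohort` is `NULL`.
#' @param seed Integer seed.
#' @param n_days Trial duration (default 19 days).
#' @return A [trial_dataset()] with `n_days` INR rows and `n_days` dose rows
#'   per patient.
#' @export
run_mipd_trial <- function(config = ct_config(), agent = zero_dose_agent(),
                           cohort = NULL, n = 1000, seed = 1, n_days = 19) {
  stopifnot(inherits(agent, "dosing_agent"))
  set.seed(seed)
  if (is.null(cohort))
    cohort <- sample_cohort(config$population, config$demo, n)
  n <- nrow(cohort$covariates)
  meas <- list(); doses <- list()
  for (i in seq_len(n)) {
    if (!is.null(agent$reset)) agent$reset()
    chi <- cohort$profiles[[i]]
    decide <- function(day, meas_so_far, doses_so_far) {
      rec <- monitoring_record(
        tibble::tibble(time_h = 24 * (0:day), value = meas_so_far),
        dosing_regimen(doses_so_far, 24 * (seq_along(doses_so_far) - 1)),
        patient_id = i)
      d <- agent$next_dose(chi, rec, config$y_star, day)
      if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d < 0)
        stop(sprintf("agent '%s' returned an invalid dose on day %d",
                     agent$name, day), call. = FALSE)
      round_dose(d, config)
    }
    res <- run_daily_protocol(cohort$parameters[[i]], n_days, 0:(n_days - 1),
                              config, decide, stop_rule = FALSE)
    meas[[i]] <- tibble::tibble(patient_id = i, observable = "INR",
                                time_h = res$measurement_time, value = res$inr)
    doses[[i]] <- tibble::tibble(patient_id = i, time_h = res$dose_time,
                                 dose_mg = res$doses)
  }
  trial_dataset(do.call(rbind, meas), do.call(rbind, doses),
                cohort$covariates,
                metadata = list(trial = "mipd", agent = agent$name,
                                seed = seed,
                                config_hash = config_hash(config),
                                stopped = integer(0)))
}
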