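#' Treatment-response emulator for RL training
#'
#' Wraps a population model as the environment the RL agent trains against:
#' virtual patients are drawn from the population and demographics, the state
#' advances one day per dose, and observations are INR measurements with the
#' measurement layer applied (no execution delays; inter-occasion variability
#' only if `use_iov` is set). In the full workflow the emulator is built from
#' the *fitted* PKPD population model ([posterior_emulator()]), so the RL
#' agent learns from the same information the PKPD agent has -- never from
#' the clinical-trial model's hidden truth.
#'
#' @param config A [ct_config()]; supplies population, demographics and
#'   measurement noise.
#' @param use_iov If `TRUE` the emulator also applies daily occasion
#'   multipliers. Default `FALSE` (the fitted PKPD model carries no IOV).
#' @return An emulator: list of functions `sample_patient()`, `reset(psi)`,
#'   `step(state, psi, t0, dose)`, `observe(state, psi)`.
#' @export
ct_emulator <- function(config = ct_config(), use_iov = FALSE) {
  emulator_error <- function(e)
    stop(errorCondition(conditionMessage(e),
                        class = c("mipdtrial_emulator_error", "error",
                                  "condition")))
  list(
    sample_patient = function() {
      cohort <- sample_cohort(config$population, config$demo, 1)
      list(chi = cohort$profiles[[1]], psi = cohort$parameters[[1]])
    },
    reset = function(psi) wf_initial_state(psi),
    step = function(state, psi, t0, dose) {
      eta <- if (use_iov)
        sample_occasions(1, config$iov)$eta_by_day else 1
      tryCatch(
        wf_step_cpp(state, psi_vector(psi), t0, t0 + 24, dose, t0, eta,
                    1e-8, 1e-10),
        error = emulator_error)
    },
    observe = function(state, psi) {
      sample_measurement(wf_inr_cpp(state, psi_vector(psi)),
                         config$measurement)
    })
}

#' Emulator built from a fitted hierarchical posterior
#'
#' Replaces the configuration's population model with the posterior point
#' estimates of [fit_population()] and delegates to [ct_emulator()]. This is
#' the emulator the Deep RL agent is trained on in the standard workflow: the
#' RL model learns indirectly from the trial data through the fitted PKPD
#' model.
#'
#' @param posterior A `hierarchical_posterior` from [fit_population()].
#' @param config A [ct_config()] for demographics and measurement noise.
#' @return An emulator (see [ct_emulator()]).
#' @export
posterior_emulator <- function(posterior, config = ct_config()) {
  cfg <- config
  cfg$population <- population_from_posterior(posterior, config$population)
  ct_emulator(cfg, use_iov = FALSE)
}
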