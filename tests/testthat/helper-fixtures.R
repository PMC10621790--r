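# shared fixtures: small, fast configurations used across test files

# deterministic clinical-trial model: no IIV, IOV, execution delays or noise
quiet_config <- function(...) {
  ct_config(
    population = population_parameters(omegas = c(ke = 0, EC50 = 0,
                                                  MTT = 0, V = 0)),
    iov = iov_config(sigma_eta = 0),
    execution = execution_config(tau_min = 0),
    measurement = measurement_config(sigma = 0),
    ...)
}

# closed-form concentration after a single oral dose (Bateman function),
# independent of the ODE solver
bateman_conc <- function(t, dose, psi) {
  dose * psi$ka / (psi$V * (psi$ka - psi$ke)) *
    (exp(-psi$ke * t) - exp(-psi$ka * t))
}

# a hierarchical posterior with known point estimates, built without MCMC;
# used to unit-test the individualisation layer in isolation
fake_posterior <- function(theta = list(ke_typ = 0.018, ec50_typ = 6.4204,
                                        omega_ke = 0.25, omega_ec50 = 0.30,
                                        omega_mtt = 0.20, omega_v = 0.10,
                                        sigma_conc = 0.1, sigma_inr = 0.1),
                           base = population_parameters()) {
  pn <- names(theta)
  samples <- array(rep(unlist(theta), each = 10), c(10, length(pn), 2),
                   dimnames = list(NULL, pn, NULL))
  structure(list(samples = samples,
                 summary = tibble::tibble(parameter = pn,
                                          mean = unlist(theta)),
                 rhat = stats::setNames(rep(1, length(pn)), pn),
                 ess = stats::setNames(rep(20, length(pn)), pn),
                 theta_hat = theta, converged = TRUE,
                 base_population = base, n_patients = 0,
                 warmup = 0, draws = 10, n_chains = 2, seed = 0),
            class = "hierarchical_posterior")
}

# a tiny deterministic cohort for protocol tests
tiny_cohort <- function(n = 3, config = quiet_config(), seed = 42) {
  sample_cohort(config$population, config$demo, n, seed = seed)
}
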