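# MIPD method 3: hierarchical Bayesian fit of the warfarin PKPD model to
# pre-MIPD trial data, per-patient MAP individualisation from monitoring
# data, and CMA-ES dosing-regimen optimisation against the target INR.
#
# The MIPD-internal model is the same reduced PKPD structure as the clinical
# trial model but, like any model fitted to sparse monitoring data, is blind
# to inter-occasion variability and execution delays; their contribution is
# absorbed into the residual noise.

# random-effect order used throughout this module
RE_NAMES <- c("ke", "EC50", "MTT", "V")

# flatten trial datasets into per-patient fitting records
fit_records <- function(datasets) {
  if (inherits(datasets, "trial_dataset")) datasets <- list(datasets)
  recs <- list()
  for (ds in datasets) {
    stopifnot(inherits(ds, "trial_dataset"))
    phase3_like <- identical(ds$metadata$trial, "phase3")
    for (id in unique(ds$covariates$patient_id)) {
      cv <- ds$covariates[ds$covariates$patient_id == id, ]
      m <- ds$measurements[ds$measurements$patient_id == id, ]
      d <- ds$doses[ds$doses$patient_id == id, ]
      if (nrow(m) == 0) next
      if (phase3_like && nrow(d) == 1) {
        # maintenance-dose record: approximate the trial with constant daily
        # dosing at the maintenance dose up to the measurement day
        days <- floor(max(m$time_h) / 24)
        d <- tibble::tibble(patient_id = id, time_h = 24 * (0:days),
                            dose_mg = d$dose_mg[1])
      }
      ord <- order(m$time_h)
      recs[[length(recs) + 1]] <- list(
        chi = covariate_profile(cv$cyp2c9, cv$vkorc1, cv$age),
        dose_amt = d$dose_mg, dose_t = d$time_h,
        obs_t = m$time_h[ord], obs_val = m$value[ord],
        obs_inr = (m$observable == "INR")[ord])
    }
  }
  recs
}

# residuals (log observed - log predicted) for one record under psi
record_residuals <- function(rec, psi_v) {
  # likelihood evaluations tolerate a looser ODE tolerance than reporting
  # paths: 1e-6 relative precision is invisible under a 0.1 residual scale
  pred <- wf_simulate_cpp(psi_v, rec$dose_amt, rec$dose_t, 1, rec$obs_t,
                          1e-6, 1e-8)
  yhat <- ifelse(rec$obs_inr, pred[, 2], pred[, 1])
  log(rec$obs_val) - log(pmax(yhat, 1e-12))
}

# psi vector for record i given population-level log typicals and a
# random-effect vector b (order RE_NAMES); fixed structure from `fixed`
record_psi <- function(fixed, mult_ke, mult_ec50, ltk, lte, b) {
  c(fixed$ka, exp(ltk + b[1]) * mult_ke, fixed$V * exp(b[4]),
    exp(lte + b[2]) * mult_ec50, fixed$gamma, fixed$MTT * exp(b[3]),
    fixed$n_transit, fixed$inr_base, fixed$inr_max, fixed$lam)
}

#' Fit the hierarchical PKPD population model to pre-MIPD trial data
#'
#' Joint Bayesian fit over warfarin concentration (phase I) and INR
#' (phase II/III) observations with lognormal measurement error. The
#' population structure mirrors the clinical-trial population model:
#' covariate multipliers and the remaining typical values are treated as
#' known structural prior knowledge, while the typical elimination rate and
#' EC50, the four random-effect SDs (ke, EC50, MTT, V) and the two residual
#' scales are estimated, together with per-patient lognormal random effects.
#' Sampling is Metropolis-within-Gibbs with adaptive-covariance random-walk
#' proposals (per-patient blocks for the random effects and a joint block for
#' the typical values, both shaped by running posterior covariances during
#' warmup), non-centring recentring moves along the typical/random-effect
#' ridge, and conjugate inverse-gamma Gibbs updates for variances. Convergence is
#' summarised with split R-hat and effective sample sizes; R-hat >= 1.05 on
#' any retained parameter triggers a warning and flags the posterior.
#'
#' @param datasets A [trial_dataset()] or list of them (phases I-III).
#' @param base_population A [population_parameters()] holding the known
#'   structure and the prior centres for the typical values.
#' @param n_chains,warmup,draws Sampler settings (default 3 chains, 1000
#'   warmup + 1000 retained draws each).
#' @param prior_sd_log_typical Normal prior SD on the log typical values.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return A `hierarchical_posterior`: retained draws of the eight population
#'   parameters, posterior summary, split R-hat, effective sample sizes,
#'   point estimates (`theta_hat`, posterior means) and the fixed structure.
#' @export
fit_population <- function(datasets, base_population = population_parameters(),
                           n_chains = 3, warmup = 1000, draws = 1000,
                           prior_sd_log_typical = 0.5, seed = 1) {
  recs <- fit_records(datasets)
  n <- length(recs)
  if (n < 2) stop("need at least 2 patients to fit the population model",
                  call. = FALSE)
  fixed <- base_population$typical
  mult_ke <- vapply(recs, function(r)
    base_population$cyp2c9_ke_mult[[r$chi$cyp2c9]] *
      (1 + base_population$age_slope * (r$chi$age - REFERENCE_AGE)), 0)
  mult_ec50 <- vapply(recs, function(r)
    base_population$vkorc1_ec50_mult[[r$chi$vkorc1]], 0)
  ltk0 <- log(fixed$ke); lte0 <- log(fixed$EC50)
  # weakly-informative conjugate priors: E[omega^2] = 0.04, E[sigma^2] = 0.01
  a_om <- 2.5; b_om <- 0.06
  a_s <- 2.5; b_s <- 0.015
  rinvgamma <- function(a, b) 1 / stats::rgamma(1, shape = a, rate = b)

  param_names <- c("ke_typ", "ec50_typ", "omega_ke", "omega_ec50",
                   "omega_mtt", "omega_v", "sigma_conc", "sigma_inr")
  all_draws <- array(NA_real_, c(draws, length(param_names), n_chains),
                     dimnames = list(NULL, param_names, NULL))
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(chain_seeds[ch])
    ltk <- ltk0 + stats::rnorm(1, 0, 0.2)
    lte <- lte0 + stats::rnorm(1, 0, 0.2)
    b <- matrix(0, n, 4)
    om2 <- rep(0.04, 4)
    s2c <- 0.01; s2i <- 0.01
    res <- vector("list", n)
    for (i in seq_len(n))
      res[[i]] <- record_residuals(recs[[i]], record_psi(
        fixed, mult_ke[i], mult_ec50[i], ltk, lte, b[i, ]))
    ll_from_res <- function(r, inr) {
      -sum(!inr) * 0.5 * log(s2c) - sum(r[!inr]^2) / (2 * s2c) -
        sum(inr) * 0.5 * log(s2i) - sum(r[inr]^2) / (2 * s2i)
    }
    ll <- vapply(seq_len(n), function(i)
      ll_from_res(res[[i]], recs[[i]]$obs_inr), 0)
    scale_b <- rep(0.3, n); scale_t <- 0.05
    # adaptive-covariance proposals: per-patient running moments of b and of
    # the typical-value block, used (after a burn-in of the adaptation) to
    # shape the random-walk steps
    mu_b <- matrix(0, n, 4); m2_b <- array(0, c(n, 4, 4)); cnt <- 0
    chol_b <- replicate(n, diag(4), simplify = FALSE)
    mu_t <- c(ltk, lte); m2_t <- matrix(0, 2, 2); chol_t <- diag(2)
    total <- warmup + draws
    for (it in seq_len(total)) {
      adapt <- it <= warmup
      rate <- min(0.1, 2 / sqrt(it))
      # per-patient random-effect blocks
      for (i in seq_len(n)) {
        bp <- b[i, ] + scale_b[i] *
          as.vector(crossprod(chol_b[[i]], stats::rnorm(4)))
        rp <- record_residuals(recs[[i]], record_psi(
          fixed, mult_ke[i], mult_ec50[i], ltk, lte, bp))
        llp <- ll_from_res(rp, recs[[i]]$obs_inr)
        lpr <- sum(stats::dnorm(bp, 0, sqrt(om2), log = TRUE)) -
          sum(stats::dnorm(b[i, ], 0, sqrt(om2), log = TRUE))
        acc <- log(stats::runif(1)) < llp - ll[i] + lpr
        if (acc) { b[i, ] <- bp; res[[i]] <- rp; ll[i] <- llp }
        if (adapt) scale_b[i] <- exp(log(scale_b[i]) + rate * (acc - 0.3))
      }
      # joint typical-value block
      prop <- c(ltk, lte) + scale_t *
        as.vector(crossprod(chol_t, stats::rnorm(2)))
      resp <- vector("list", n)
      llp <- numeric(n)
      for (i in seq_len(n)) {
        resp[[i]] <- record_residuals(recs[[i]], record_psi(
          fixed, mult_ke[i], mult_ec50[i], prop[1], prop[2], b[i, ]))
        llp[i] <- ll_from_res(resp[[i]], recs[[i]]$obs_inr)
      }
      lpr <- stats::dnorm(prop[1], ltk0, prior_sd_log_typical, log = TRUE) +
        stats::dnorm(prop[2], lte0, prior_sd_log_typical, log = TRUE) -
        stats::dnorm(ltk, ltk0, prior_sd_log_typical, log = TRUE) -
        stats::dnorm(lte, lte0, prior_sd_log_typical, log = TRUE)
      acc <- log(stats::runif(1)) < sum(llp) - sum(ll) + lpr
      if (acc) { ltk <- prop[1]; lte <- prop[2]; res <- resp; ll <- llp }
      if (adapt) scale_t <- exp(log(scale_t) + rate * (acc - 0.3))
      # recentring moves: shift a typical value and counter-shift the random
      # effects (likelihood-invariant, decorrelates the hierarchy)
      for (k in 1:2) {
        del <- stats::rnorm(1, 0, 0.1)
        cur_t <- if (k == 1) ltk else lte
        t0 <- if (k == 1) ltk0 else lte0
        lr <- stats::dnorm(cur_t + del, t0, prior_sd_log_typical, log = TRUE) -
          stats::dnorm(cur_t, t0, prior_sd_log_typical, log = TRUE) +
          sum(stats::dnorm(b[, k] - del, 0, sqrt(om2[k]), log = TRUE)) -
          sum(stats::dnorm(b[, k], 0, sqrt(om2[k]), log = TRUE))
        if (log(stats::runif(1)) < lr) {
          if (k == 1) ltk <- ltk + del else lte <- lte + del
          b[, k] <- b[, k] - del
        }
      }
      # conjugate Gibbs updates for variances
      for (k in 1:4)
        om2[k] <- rinvgamma(a_om + n / 2, b_om + sum(b[, k]^2) / 2)
      rc2 <- 0; nc <- 0; ri2 <- 0; ni <- 0
      for (i in seq_len(n)) {
        inr <- recs[[i]]$obs_inr
        rc2 <- rc2 + sum(res[[i]][!inr]^2); nc <- nc + sum(!inr)
        ri2 <- ri2 + sum(res[[i]][inr]^2); ni <- ni + sum(inr)
      }
      if (nc > 0) s2c <- rinvgamma(a_s + nc / 2, b_s + rc2 / 2)
      if (ni > 0) s2i <- rinvgamma(a_s + ni / 2, b_s + ri2 / 2)
      # update adaptation moments; refresh proposal shapes during warmup
      if (adapt) {
        cnt <- cnt + 1
        for (i in seq_len(n)) {
          d <- b[i, ] - mu_b[i, ]
          mu_b[i, ] <- mu_b[i, ] + d / cnt
          m2_b[i, , ] <- m2_b[i, , ] + tcrossprod(d, b[i, ] - mu_b[i, ])
        }
        dt_ <- c(ltk, lte) - mu_t
        mu_t <- mu_t + dt_ / cnt
        m2_t <- m2_t + tcrossprod(dt_, c(ltk, lte) - mu_t)
        if (cnt > 200 && it %% 25 == 0) {
          for (i in seq_len(n)) {
            cv <- m2_b[i, , ] / (cnt - 1) + 1e-6 * diag(4)
            chf <- tryCatch(chol(cv), error = function(e) NULL)
            if (!is.null(chf))
              chol_b[[i]] <- chf / exp(mean(log(diag(chf)))) # unit volume
          }
          cv <- m2_t / (cnt - 1) + 1e-8 * diag(2)
          chf <- tryCatch(chol(cv), error = function(e) NULL)
          if (!is.null(chf)) chol_t <- chf / exp(mean(log(diag(chf))))
        }
      }
      # refresh cached log-likelihoods for the new variances
      ll <- vapply(seq_len(n), function(i)
        ll_from_res(res[[i]], recs[[i]]$obs_inr), 0)
      if (it > warmup) {
        vals <- c(exp(ltk), exp(lte), sqrt(om2), sqrt(s2c), sqrt(s2i))
        if (any(!is.finite(vals)))
          stop(sprintf(
            "sampler produced non-finite draws (chain %d, iteration %d): %s",
            ch, it, paste(signif(vals, 4), collapse = " ")), call. = FALSE)
        all_draws[it - warmup, , ch] <- vals
      }
    }
  }
  rhat <- apply(all_draws, 2, split_rhat)
  ess <- apply(all_draws, 2, ess_basic)
  flat <- apply(all_draws, 2, identity)
  theta_hat <- as.list(colMeans(flat))
  summ <- tibble::tibble(parameter = param_names,
                         mean = colMeans(flat),
                         sd = apply(flat, 2, sd),
                         q05 = apply(flat, 2, quantile, 0.05),
                         q95 = apply(flat, 2, quantile, 0.95),
                         rhat = rhat, ess = ess)
  converged <- all(is.finite(rhat)) && all(rhat < 1.05)
  if (!converged)
    warning(sprintf("possible non-convergence: max split R-hat = %.3f",
                    max(rhat)), call. = FALSE)
  structure(list(samples = all_draws, summary = summ, rhat = rhat, ess = ess,
                 theta_hat = theta_hat, converged = converged,
                 base_population = base_population,
                 n_patients = n, warmup = warmup, draws = draws,
                 n_chains = n_chains, seed = seed),
            class = "hierarchical_posterior")
}

#' @export
print.hierarchical_posterior <- function(x, ...) {
  cat(sprintf("<hierarchical_posterior: %d patients, %d chains x %d draws%s>\n",
              x$n_patients, x$n_chains, x$draws,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

# split R-hat over a draws x chains matrix
split_rhat <- function(x) {
  x <- as.matrix(x)
  half <- floor(nrow(x) / 2)
  segs <- cbind(x[seq_len(half), , drop = FALSE],
                x[(nrow(x) - half + 1):nrow(x), , drop = FALSE])
  m <- ncol(segs); nn <- nrow(segs)
  mu <- colMeans(segs)
  B <- nn * var(mu)
  W <- mean(apply(segs, 2, var))
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# initial-positive-sequence effective sample size, summed over chains
ess_basic <- function(x) {
  x <- as.matrix(x)
  sum(apply(x, 2, function(v) {
    nn <- length(v)
    if (var(v) == 0) return(nn)
    rho <- stats::acf(v, lag.max = min(200, nn - 1), plot = FALSE)$acf[-1]
    neg <- which(rho < 0)
    if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
    nn / (1 + 2 * sum(rho))
  }))
}

#' Population model implied by a fitted posterior
#'
#' Point estimates (posterior means) of the typical elimination rate, typical
#' EC50 and the four random-effect SDs replace the corresponding entries of
#' the base population structure.
#'
#' @param posterior A `hierarchical_posterior`.
#' @param base A [population_parameters()] supplying the fixed structure;
#'   defaults to the one stored in the posterior.
#' @return A [population_parameters()] object.
#' @export
population_from_posterior <- function(posterior, base = NULL) {
  stopifnot(inherits(posterior, "hierarchical_posterior"))
  if (is.null(base)) base <- posterior$base_population
  th <- posterior$theta_hat
  typ <- base$typical
  typ$ke <- th$ke_typ
  typ$EC50 <- th$ec50_typ
  population_parameters(
    typical = typ,
    cyp2c9_ke_mult = base$cyp2c9_ke_mult,
    vkorc1_ec50_mult = base$vkorc1_ec50_mult,
    age_slope = base$age_slope,
    omegas = c(ke = th$omega_ke, EC50 = th$omega_ec50, MTT = th$omega_mtt,
               V = th$omega_v))
}

# negative log-posterior of the random effects b given a monitoring record
map_objective <- function(posterior, chi, record) {
  pop <- population_from_posterior(posterior)
  typ <- typical_parameters(pop, chi)
  fixed <- posterior$base_population$typical
  omg <- c(posterior$theta_hat$omega_ke, posterior$theta_hat$omega_ec50,
           posterior$theta_hat$omega_mtt, posterior$theta_hat$omega_v)
  sig <- posterior$theta_hat$sigma_inr
  m <- record$measurements
  reg <- record$regimen_so_far
  typ_v <- psi_vector(typ)
  function(b) {
    psi_v <- typ_v
    psi_v[2] <- typ_v[2] * exp(b[1])  # ke
    psi_v[4] <- typ_v[4] * exp(b[2])  # EC50
    psi_v[6] <- typ_v[6] * exp(b[3])  # MTT
    psi_v[3] <- typ_v[3] * exp(b[4])  # V
    nlp <- -sum(stats::dnorm(b, 0, omg, log = TRUE))
    if (nrow(m) > 0) {
      pred <- wf_simulate_cpp(psi_v, reg$dose_mg, reg$time_h, 1,
                              m$time_h, 1e-8, 1e-10)[, 2]
      nlp <- nlp - sum(stats::dnorm(log(m$value), log(pmax(pred, 1e-12)),
                                    sig, log = TRUE))
    }
    nlp
  }
}

#' MAP individualisation of the PKPD model from monitoring data
#'
#' Maximises the posterior of the patient-specific random effects (on ke,
#' EC50, MTT and V) given the individual's INR monitoring record, using the
#' fitted population model and the covariates as prior knowledge. With an
#' empty record the MAP estimate equals the subpopulation-typical parameters
#' (the prior mode). Optimisation is gradient-free (Nelder-Mead) from five
#' starts: the prior mode and the mode perturbed by plus/minus one omega on
#' ke and on EC50.
#'
#' @param posterior A `hierarchical_posterior` from [fit_population()].
#' @param chi A [covariate_profile()].
#' @param record A [monitoring_record()]; may be empty.
#' @param maxit Nelder-Mead iteration budget per start.
#' @param reltol Nelder-Mead relative convergence tolerance.
#' @param starts Optional list of start vectors replacing the default five
#'   (used by the sequential agent to warm start from the previous day's
#'   optimum).
#' @return An `individual_posterior`: MAP parameters `psi_hat`, random
#'   effects `b_hat`, the negative log-posterior `nlp`, and the inputs.
#' @export
fit_individual_map <- function(posterior, chi, record, maxit = 300,
                               reltol = 1e-7, starts = NULL) {
  stopifnot(inherits(posterior, "hierarchical_posterior"),
            inherits(record, "monitoring_record"))
  pop <- population_from_posterior(posterior)
  typ <- typical_parameters(pop, chi)
  obj <- map_objective(posterior, chi, record)
  if (nrow(record$measurements) == 0) {
    return(structure(list(psi_hat = typ, b_hat = rep(0, 4), nlp = obj(rep(0, 4)),
                          chi = chi, record = record, starts = 0),
                     class = "individual_posterior"))
  }
  if (is.null(starts)) {
    omg_ke <- posterior$theta_hat$omega_ke
    omg_ec <- posterior$theta_hat$omega_ec50
    starts <- list(rep(0, 4),
                   c(omg_ke, 0, 0, 0), c(-omg_ke, 0, 0, 0),
                   c(0, omg_ec, 0, 0), c(0, -omg_ec, 0, 0))
  }
  best <- NULL
  failures <- 0
  for (s in starts) {
    fit <- tryCatch(stats::optim(s, obj, method = "Nelder-Mead",
                                 control = list(maxit = maxit,
                                                reltol = reltol)),
                    error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1; next }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("MAP optimisation failed from all starts", call. = FALSE)
  b <- best$par
  psi <- typ
  psi$ke <- typ$ke * exp(b[1]); psi$EC50 <- typ$EC50 * exp(b[2])
  psi$MTT <- typ$MTT * exp(b[3]); psi$V <- typ$V * exp(b[4])
  structure(list(psi_hat = psi, b_hat = b, nlp = best$value, chi = chi,
                 record = record, starts = length(starts) - failures),
            class = "individual_posterior")
}

#' Evaluate the individual negative log-posterior at given random effects
#'
#' Diagnostic helper: the objective minimised by [fit_individual_map()],
#' evaluated at an arbitrary random-effect vector (order ke, EC50, MTT, V).
#'
#' @inheritParams fit_individual_map
#' @param b Numeric random-effect vector of length 4.
#' @return The negative log-posterior value.
#' @export
map_nlp <- function(posterior, chi, record, b) map_objective(posterior, chi, record)(b)

#' Optimise the remaining dosing regimen against the target INR
#'
#' CMA-ES minimisation of the sum of squared deviations between the
#' individualised model's predicted INR (the morning after each remaining
#' dose) and the target, over the remaining daily doses within bounds.
#' Candidate regimens are repaired onto the dose box; the all-zero regimen
#' and the warm start are always evaluated, and the best regimen found is
#' returned (with a warning if the iteration budget was exhausted without
#' convergence). If the individualised model predicts no drug effect
#' (`inr_max = 0`) the objective is dose-independent and the documented
#' fallback -- the all-zero regimen -- is returned.
#'
#' @param individual An `individual_posterior` from [fit_individual_map()].
#' @param y_star Target INR.
#' @param horizon_days Number of remaining daily doses to plan (>= 1).
#' @param dose_bounds Dose box in mg (default 0 to 30).
#' @param dose_step Rounding granularity (mg).
#' @param current_day 0-based index of the first planned dose day; defaults
#'   to the number of doses already administered in the record.
#' @param warm_start Optional start vector (previous day's solution).
#' @param popsize,max_iter CMA-ES population size and iteration budget.
#' @param patience CMA-ES stagnation patience (iterations without
#'   improvement before stopping).
#' @return A nominal [dosing_regimen()] of the planned daily doses with
#'   attributes `objective` (achieved value) and `converged`.
#' @export
optimise_regimen <- function(individual, y_star = 2.5, horizon_days,
                             dose_bounds = c(0, 30), dose_step = 0.5,
                             current_day = NULL, warm_start = NULL,
                             popsize = 8, max_iter = 200, patience = 25) {
  stopifnot(inherits(individual, "individual_posterior"), horizon_days >= 1)
  reg <- individual$record$regimen_so_far
  j <- if (is.null(current_day)) length(reg$dose_mg) else current_day
  plan_t <- 24 * (j:(j + horizon_days - 1))
  pred_t <- plan_t + 24
  psi <- individual$psi_hat
  if (psi$inr_max == 0) {
    out <- dosing_regimen(rep(0, horizon_days), plan_t)
    attr(out, "objective") <- horizon_days * (psi$inr_base - y_star)^2
    attr(out, "converged") <- TRUE
    return(out)
  }
  psi_v <- psi_vector(psi)
  fn <- function(d) {
    inr <- wf_simulate_cpp(psi_v, c(reg$dose_mg, d), c(reg$time_h, plan_t),
                           1, pred_t, 1e-8, 1e-10)[, 2]
    sum((inr - y_star)^2)
  }
  x0 <- if (!is.null(warm_start)) rep_len(warm_start, horizon_days)
    else rep(5, horizon_days)
  fit <- cma_es(fn, x0, sigma0 = 2, lower = dose_bounds[1],
                upper = dose_bounds[2], popsize = popsize,
                max_iter = max_iter, patience = patience)
  if (!fit$converged)
    warning("regimen optimiser exhausted its budget; returning best found",
            call. = FALSE)
  doses <- pmin(dose_bounds[2],
                pmax(dose_bounds[1], round(fit$par / dose_step) * dose_step))
  out <- dosing_regimen(doses, plan_t)
  attr(out, "objective") <- fit$value
  attr(out, "raw") <- fit$par
  attr(out, "converged") <- fit$converged
  out
}

#' One step of the PKPD dosing agent
#'
#' Fits the individual MAP parameters from the monitoring record, optimises
#' the dosing regimen for the remaining horizon, and returns the first
#' planned dose together with the full predicted regimen (the iteratively
#' refined regimen function).
#'
#' @inheritParams fit_individual_map
#' @param y_star Target INR.
#' @param day 0-based current day.
#' @param horizon_total Total trial duration in days (plans `horizon_total -
#'   day` doses).
#' @param warm_start,popsize,max_iter Passed to [optimise_regimen()].
#' @param map_starts Optional start list passed to [fit_individual_map()].
#' @return List with `dose` (mg), `regimen` (planned [dosing_regimen()]) and
#'   `individual` (the MAP fit).
#' @export
pkpd_agent_step <- function(posterior, chi, record, y_star = 2.5, day = 0,
                            horizon_total = 19, warm_start = NULL,
                            popsize = 8, max_iter = 200, patience = 25,
                            map_starts = NULL) {
  ind <- fit_individual_map(posterior, chi, record, starts = map_starts)
  reg <- optimise_regimen(ind, y_star = y_star,
                          horizon_days = horizon_total - day,
                          current_day = day, warm_start = warm_start,
                          popsize = popsize, max_iter = max_iter,
                          patience = patience)
  list(dose = reg$dose_mg[1], regimen = reg, individual = ind)
}

#' Dosing agent wrapping the Bayesian PKPD model
#'
#' Each day the agent re-fits the individual MAP parameters from all
#' available monitoring data and re-optimises the remaining regimen, warm
#' starting from the previous day's solution shifted by one day. The full
#' predicted regimen of every day is logged for diagnostics and can be
#' retrieved with the agent's `logged_regimens()` accessor.
#'
#' @param posterior A `hierarchical_posterior`.
#' @param horizon_total Trial duration the agent plans over (days).
#' @param popsize,max_iter CMA-ES settings per daily re-optimisation.
#' @param patience CMA-ES stagnation patience; the agent default (15) is
#'   tighter than the standalone optimiser's because warm-started daily
#'   re-optimisations start near the optimum.
#' @return A [dosing_agent()] with extra element `logged_regimens`.
#' @export
pkpd_agent <- function(posterior, horizon_total = 19, popsize = 8,
                       max_iter = 200, patience = 15) {
  store <- new.env(parent = emptyenv())
  store$warm <- NULL
  store$b <- NULL
  store$log <- list()
  agent <- dosing_agent(
    "pkpd",
    next_dose = function(chi, record, y_star, day) {
      warm <- if (!is.null(store$warm) && length(store$warm) > 1)
        store$warm[-1] else NULL
      # early days use the full multi-start; later refits warm start from the
      # previous day's optimum (plus the prior mode as a safeguard)
      map_starts <- if (day > 2 && !is.null(store$b))
        list(store$b, rep(0, 4)) else NULL
      step <- pkpd_agent_step(posterior, chi, record, y_star = y_star,
                              day = day, horizon_total = horizon_total,
                              warm_start = warm, popsize = popsize,
                              max_iter = max_iter, patience = patience,
                              map_starts = map_starts)
      store$warm <- attr(step$regimen, "raw")
      store$b <- step$individual$b_hat
      store$log[[length(store$log) + 1]] <-
        list(day = day, patient_id = record$patient_id,
             regimen = step$regimen)
      step$dose
    },
    reset = function() { store$warm <- NULL; store$b <- NULL })
  agent$logged_regimens <- function() store$log
  agent
}

#' Serialise / restore a hierarchical posterior as JSON
#'
#' @param posterior A `hierarchical_posterior`.
#' @param path File path (`.json`).
#' @return `write_posterior` returns `path` invisibly; `read_posterior` the
#'   posterior (with the flattened draws).
#' @export
write_posterior <- function(posterior, path) {
  x <- list(samples = lapply(seq_len(dim(posterior$samples)[3]), function(ch)
    as.data.frame(posterior$samples[, , ch])),
    theta_hat = posterior$theta_hat, rhat = as.list(posterior$rhat),
    ess = as.list(posterior$ess), converged = posterior$converged,
    n_patients = posterior$n_patients, warmup = posterior$warmup,
    draws = posterior$draws, n_chains = posterior$n_chains,
    seed = posterior$seed,
    base_population = list(
      typical = unclass(posterior$base_population$typical),
      cyp2c9_ke_mult = as.list(posterior$base_population$cyp2c9_ke_mult),
      vkorc1_ec50_mult = as.list(posterior$base_population$vkorc1_ec50_mult),
      age_slope = posterior$base_population$age_slope,
      omegas = as.list(posterior$base_population$omegas)))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  n_chains <- length(x$samples)
  draws <- nrow(x$samples[[1]])
  pn <- colnames(x$samples[[1]])
  samples <- array(NA_real_, c(draws, length(pn), n_chains),
                   dimnames = list(NULL, pn, NULL))
  for (ch in seq_len(n_chains)) samples[, , ch] <- as.matrix(x$samples[[ch]])
  bp <- population_parameters(
    typical = do.call(individual_parameters, as.list(x$base_population$typical)),
    cyp2c9_ke_mult = unlist(x$base_population$cyp2c9_ke_mult),
    vkorc1_ec50_mult = unlist(x$base_population$vkorc1_ec50_mult),
    age_slope = x$base_population$age_slope,
    omegas = unlist(x$base_population$omegas))
  flat <- apply(samples, 2, identity)
  summ <- tibble::tibble(parameter = pn, mean = colMeans(flat),
                         sd = apply(flat, 2, sd),
                         q05 = apply(flat, 2, quantile, 0.05),
                         q95 = apply(flat, 2, quantile, 0.95),
                         rhat = unlist(x$rhat), ess = unlist(x$ess))
  structure(list(samples = samples, summary = summ, rhat = unlist(x$rhat),
                 ess = unlist(x$ess), theta_hat = x$theta_hat,
                 converged = x$converged, base_population = bp,
                 n_patients = x$n_patients, warmup = x$warmup,
                 draws = x$draws, n_chains = n_chains, seed = x$seed),
            class = "hierarchical_posterior")
}
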