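#' Mechanistic model parameters of one virtual patient
#'
#' Constructs and validates the parameter set \eqn{\psi} of the reduced
#' warfarin PKPD model: one-compartment pharmacokinetics with first-order
#' absorption, an inhibitory Hill effect of the central concentration on the
#' production of a clotting-activity transit chain, and an INR readout.
#'
#' @param ka Absorption rate (1/h).
#' @param ke Elimination rate (1/h).
#' @param V Volume of distribution (L).
#' @param EC50 Half-maximal inhibitory concentration (mg/L).
#' @param gamma Hill coefficient (dimensionless).
#' @param MTT Mean transit time of the pharmacodynamic delay chain (h).
#' @param n_transit Number of transit compartments (integer >= 1).
#' @param inr_base Baseline INR (dimensionless, >= 0.8).
#' @param inr_max Maximal INR increment at full suppression of clotting
#'   activity (dimensionless).
#' @param lam Response-shape exponent (dimensionless).
#'
#' @return An object of class `individual_parameters` (named list).
#' @export
#' @examples
#' psi <- individual_parameters()
#' psi$ke
individual_parameters <- function(ka = 1.0, ke = 0.018, V = 14, EC50 = 6.4204,
                                  gamma = 1.2, MTT = 40, n_transit = 3L,
                                  inr_base = 1.0, inr_max = 19, lam = 1.0) {
  psi <- list(ka = ka, ke = ke, V = V, EC50 = EC50, gamma = gamma, MTT = MTT,
              n_transit = as.integer(n_transit), inr_base = inr_base,
              inr_max = inr_max, lam = lam)
  validate_parameters(psi)
  structure(psi, class = "individual_parameters")
}

#' @export
print.individual_parameters <- function(x, ...) {
  cat("<individual_parameters>\n")
  for (nm in names(x)) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

validate_parameters <- function(psi) {
  pos <- c("ka", "ke", "V", "EC50", "MTT")
  for (nm in pos) {
    v <- psi[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("parameter '%s' must be a single strictly positive number",
                   nm), call. = FALSE)
  }
  if (psi$inr_base < 0.8) stop("inr_base must be >= 0.8", call. = FALSE)
  if (psi$n_transit < 1) stop("n_transit must be >= 1", call. = FALSE)
  if (psi$inr_max < 0) stop("inr_max must be >= 0", call. = FALSE)
  if (psi$gamma <= 0 || psi$lam <= 0)
    stop("gamma and lam must be strictly positive", call. = FALSE)
  invisible(psi)
}

# fixed layout shared with src/dynamics.cpp
psi_vector <- function(psi) {
  c(psi$ka, psi$ke, psi$V, psi$EC50, psi$gamma, psi$MTT, psi$n_transit,
    psi$inr_base, psi$inr_max, psi$lam)
}

#' Dosing regimen
#'
#' A sequence of (dose, time) pairs, either as planned (`nominal`) or as
#' realised after execution delays (`actual`).
#'
#' @param dose_mg Numeric vector of doses (mg), all >= 0.
#' @param time_h Numeric vector of administration times (h), non-decreasing.
#' @param kind `"nominal"` or `"actual"`.
#'
#' @return An object of class `dosing_regimen`.
#' @export
#' @examples
#' dosing_regimen(c(10, 5), c(0, 24))
dosing_regimen <- function(dose_mg = numeric(), time_h = numeric(),
                           kind = c("nominal", "actual")) {
  kind <- match.arg(kind)
  if (length(dose_mg) != length(time_h))
    stop("dose_mg and time_h must have equal length", call. = FALSE)
  if (any(dose_mg < 0)) stop("doses must be >= 0", call. = FALSE)
  if (is.unsorted(time_h)) stop("times must be non-decreasing", call. = FALSE)
  structure(list(dose_mg = as.numeric(dose_mg), time_h = as.numeric(time_h),
                 kind = kind),
            class = "dosing_regimen")
}

#' @export
print.dosing_regimen <- function(x, ...) {
  cat(sprintf("<dosing_regimen: %d %s dose(s)>\n", length(x$dose_mg), x$kind))
  invisible(x)
}

#' Daily occasion multipliers
#'
#' Inter-occasion variability enters the mechanistic model as a multiplier
#' \eqn{\eta} on the vitamin K input rate, sampled once per simulation day and
#' held constant over that day (day k spans `[24k, 24(k+1))` hours, 0-based).
#'
#' @param eta Numeric vector of strictly positive multipliers, one per day;
#'   the last entry is reused beyond the end of the vector.
#'
#' @return An object of class `occasion_series`.
#' @export
occasion_series <- function(eta = 1) {
  if (length(eta) < 1 || any(!is.finite(eta)) || any(eta <= 0))
    stop("eta multipliers must be strictly positive", call. = FALSE)
  structure(list(eta_by_day = as.numeric(eta)), class = "occasion_series")
}
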