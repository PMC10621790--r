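CYP2C9_LEVELS <- c("*1*1", "*1*2", "*1*3", "*2*2", "*2*3", "*3*3")
VKORC1_LEVELS <- c("GG", "GA", "AA")
REFERENCE_AGE <- 71

#' Covariate profile of a virtual patient
#'
#' @param cyp2c9 One of `"*1*1" "*1*2" "*1*3" "*2*2" "*2*3" "*3*3"`. CYP2C9
#'   variants reduce warfarin's elimination rate.
#' @param vkorc1 One of `"GG" "GA" "AA"`. VKORC1 A alleles reduce warfarin's
#'   EC50 (stronger inhibition at the same concentration).
#' @param age Age in years (integer >= 18).
#' @return An object of class `covariate_profile`.
#' @export
#' @examples
#' covariate_profile("*1*2", "GA", 46)
covariate_profile <- function(cyp2c9 = "*1*1", vkorc1 = "GG", age = 71) {
  if (!cyp2c9 %in% CYP2C9_LEVELS)
    stop(sprintf("unknown CYP2C9 genotype '%s'", cyp2c9), call. = FALSE)
  if (!vkorc1 %in% VKORC1_LEVELS)
    stop(sprintf("unknown VKORC1 genotype '%s'", vkorc1), call. = FALSE)
  if (!is.numeric(age) || age < 18) stop("age must be >= 18", call. = FALSE)
  structure(list(cyp2c9 = cyp2c9, vkorc1 = vkorc1, age = as.integer(age)),
            class = "covariate_profile")
}

#' Population model parameters
#'
#' Defines the mixed-effects population distribution of mechanistic
#' parameters: a reference (typical) patient, multiplicative covariate effects
#' routing CYP2C9 to the elimination rate `ke` and VKORC1 to `EC50`, a linear
#' fractional age effect on `ke`, and lognormal random effects with standard
#' deviations `omegas` on selected parameters.
#'
#' @param typical [individual_parameters()] of the reference patient
#'   (GG, *1*1, age 71).
#' @param cyp2c9_ke_mult Named multipliers on `ke` per CYP2C9 genotype
#'   (reference genotype must map to 1).
#' @param vkorc1_ec50_mult Named multipliers on `EC50` per VKORC1 genotype
#'   (reference genotype must map to 1).
#' @param age_slope Fractional change of `ke` per year relative to age 71.
#' @param omegas Named lognormal random-effect SDs; parameters not listed are
#'   fixed across individuals.
#' @return An object of class `population_parameters`.
#' @export
population_parameters <- function(
    typical = individual_parameters(),
    cyp2c9_ke_mult = c("*1*1" = 1.0, "*1*2" = 0.73, "*1*3" = 0.40,
                       "*2*2" = 0.55, "*2*3" = 0.35, "*3*3" = 0.20),
    vkorc1_ec50_mult = c(GG = 1.0, GA = 0.60, AA = 0.35),
    age_slope = -0.01,
    omegas = c(ke = 0.25, EC50 = 0.30, MTT = 0.20, V = 0.10)) {
  stopifnot(inherits(typical, "individual_parameters"))
  if (!setequal(names(cyp2c9_ke_mult), CYP2C9_LEVELS))
    stop("cyp2c9_ke_mult must name all six CYP2C9 genotypes", call. = FALSE)
  if (!setequal(names(vkorc1_ec50_mult), VKORC1_LEVELS))
    stop("vkorc1_ec50_mult must name all three VKORC1 genotypes",
         call. = FALSE)
  if (any(cyp2c9_ke_mult <= 0) || any(vkorc1_ec50_mult <= 0))
    stop("covariate multipliers must be strictly positive", call. = FALSE)
  if (abs(cyp2c9_ke_mult[["*1*1"]] - 1) > 1e-12 ||
      abs(vkorc1_ec50_mult[["GG"]] - 1) > 1e-12)
    stop("reference-genotype multipliers must equal 1", call. = FALSE)
  if (any(omegas < 0)) stop("omegas must be >= 0", call. = FALSE)
  bad <- setdiff(names(omegas), names(typical))
  if (length(bad))
    stop("unknown parameters in omegas: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(typical = typical, cyp2c9_ke_mult = cyp2c9_ke_mult,
                 vkorc1_ec50_mult = vkorc1_ec50_mult, age_slope = age_slope,
                 omegas = omegas),
            class = "population_parameters")
}

#' Cohort demographics
#'
#' Genotype frequencies and an age distribution from which trial cohorts are
#' drawn. Default VKORC1 frequencies are Hardy-Weinberg with A-allele
#' frequency 0.40; ages are drawn as `round(Normal(65, 10))` truncated to
#' `[18, 100]`.
#'
#' @param cyp2c9_freqs,vkorc1_freqs Named probability vectors (sum to 1).
#' @param age_mean,age_sd,age_range Age distribution specification.
#' @return An object of class `demographics`.
#' @export
demographics <- function(
    cyp2c9_freqs = c("*1*1" = 0.65, "*1*2" = 0.17, "*1*3" = 0.10,
                     "*2*2" = 0.03, "*2*3" = 0.03, "*3*3" = 0.02),
    vkorc1_freqs = c(GG = 0.36, GA = 0.48, AA = 0.16),
    age_mean = 65, age_sd = 10, age_range = c(18, 100)) {
  if (!setequal(names(cyp2c9_freqs), CYP2C9_LEVELS) ||
      !setequal(names(vkorc1_freqs), VKORC1_LEVELS))
    stop("frequency vectors must name every genotype", call. = FALSE)
  if (abs(sum(cyp2c9_freqs) - 1) > 1e-12 || abs(sum(vkorc1_freqs) - 1) > 1e-12)
    stop("genotype frequencies must each sum to 1", call. = FALSE)
  structure(list(cyp2c9_freqs = cyp2c9_freqs, vkorc1_freqs = vkorc1_freqs,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range),
            class = "demographics")
}

#' Subpopulation-typical parameters for a covariate profile
#'
#' Returns the reference parameters with `ke` scaled by the CYP2C9 multiplier
#' and the age effect `1 + age_slope * (age - 71)`, and `EC50` scaled by the
#' VKORC1 multiplier. All other parameters are unchanged. The reference
#' profile (GG, *1*1, 71) maps to exactly the typical parameter set.
#'
#' @param theta A [population_parameters()] object.
#' @param chi A [covariate_profile()].
#' @return An [individual_parameters()] object.
#' @export
#' @examples
#' th <- population_parameters()
#' typical_parameters(th, covariate_profile("*1*2", "AA", 60))$EC50
typical_parameters <- function(theta, chi) {
  stopifnot(inherits(theta, "population_parameters"),
            inherits(chi, "covariate_profile"))
  psi <- theta$typical
  age_fac <- 1 + theta$age_slope * (chi$age - REFERENCE_AGE)
  if (age_fac <= 0)
    stop("age effect drives ke non-positive; check age_slope", call. = FALSE)
  psi$ke <- psi$ke * theta$cyp2c9_ke_mult[[chi$cyp2c9]] * age_fac
  psi$EC50 <- psi$EC50 * theta$vkorc1_ec50_mult[[chi$vkorc1]]
  validate_parameters(psi)
  psi
}

#' Sample one individual's parameters from the population distribution
#'
#' Each random-effect-bearing parameter is `typical * exp(omega * z)` with
#' independent standard-normal `z`; parameters without an omega are fixed at
#' their subpopulation-typical value.
#'
#' @inheritParams typical_parameters
#' @param seed Optional integer seed for a reproducible draw.
#' @return An [individual_parameters()] object.
#' @export
sample_individual <- function(theta, chi, seed = NULL) {
  with_seed(seed, {
    psi <- typical_parameters(theta, chi)
    om <- theta$omegas
    if (length(om)) {
      z <- stats::rnorm(length(om))
      for (i in seq_along(om))
        psi[[names(om)[i]]] <- psi[[names(om)[i]]] * exp(om[[i]] * z[i])
    }
    class(psi) <- "individual_parameters"
    validate_parameters(psi)
    psi
  })
}

#' Sample a virtual cohort
#'
#' Draws covariates i.i.d. from the [demographics()] and parameters through
#' [sample_individual()].
#'
#' @param theta A [population_parameters()] object.
#' @param demo A [demographics()] object.
#' @param n Cohort size (>= 1).
#' @param seed Optional integer seed.
#' @return A list with `covariates` (tibble: patient_id, cyp2c9, vkorc1, age),
#'   `profiles` (list of [covariate_profile()]) and `parameters` (list of
#'   [individual_parameters()]).
#' @export
sample_cohort <- function(theta, demo, n, seed = NULL) {
  stopifnot(inherits(demo, "demographics"), n >= 1)
  with_seed(seed, {
    cyp <- sample(names(demo$cyp2c9_freqs), n, replace = TRUE,
                  prob = demo$cyp2c9_freqs)
    vko <- sample(names(demo$vkorc1_freqs), n, replace = TRUE,
                  prob = demo$vkorc1_freqs)
    age <- pmin(pmax(round(stats::rnorm(n, demo$age_mean, demo$age_sd)),
                     demo$age_range[1]), demo$age_range[2])
    profiles <- lapply(seq_len(n), function(i)
      covariate_profile(cyp[i], vko[i], age[i]))
    params <- lapply(profiles, function(chi) sample_individual(theta, chi))
    list(covariates = tibble::tibble(patient_id = seq_len(n), cyp2c9 = cyp,
                                     vkorc1 = vko, age = as.integer(age)),
         profiles = profiles, parameters = params)
  })
}

# evaluate a block with a locally-seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
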