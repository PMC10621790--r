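test_that("reference covariates map to exactly the typical parameters", {
  th <- population_parameters()
  psi <- typical_parameters(th, covariate_profile("*1*1", "GG", 71))
  expect_identical(unclass(psi), unclass(th$typical))
})

test_that("VKORC1 A alleles reduce EC50 and CYP2C9 variants reduce ke", {
  th <- population_parameters()
  ec50 <- vapply(c("GG", "GA", "AA"), function(g)
    typical_parameters(th, covariate_profile("*1*1", g, 71))$EC50, 0)
  expect_true(ec50[["AA"]] < ec50[["GA"]] && ec50[["GA"]] < ec50[["GG"]])
  ke_11 <- typical_parameters(th, covariate_profile("*1*1", "GG", 71))$ke
  ke_13 <- typical_parameters(th, covariate_profile("*1*3", "GG", 71))$ke
  expect_lt(ke_13, ke_11)
})

test_that("unknown genotype labels are rejected", {
  expect_error(covariate_profile("*4*4", "GG", 50), "unknown CYP2C9")
  expect_error(covariate_profile("*1*1", "XX", 50), "unknown VKORC1")
})

test_that("zero omegas make sampling deterministic at the typical value", {
  th <- population_parameters(omegas = c(ke = 0, EC50 = 0, MTT = 0, V = 0))
  chi <- covariate_profile("*1*2", "GA", 46)
  psi <- sample_individual(th, chi, seed = 1)
  expect_equal(unclass(psi), unclass(typical_parameters(th, chi)))
})

test_that("sampling is reproducible given a seed", {
  th <- population_parameters()
  chi <- covariate_profile("*1*2", "GA", 46)
  expect_identical(sample_individual(th, chi, seed = 7),
                   sample_individual(th, chi, seed = 7))
})

test_that("lognormal random effects recover their omega", {
  th <- population_parameters()
  chi <- covariate_profile()
  set.seed(3)
  lke <- vapply(1:10000, function(i)
    log(sample_individual(th, chi)$ke), 0)
  # SD of log(ke) ~ omega_ke; MC standard error of the SD ~ omega/sqrt(2n)
  se <- th$omegas[["ke"]] / sqrt(2 * 10000)
  expect_lt(abs(sd(lke) - th$omegas[["ke"]]), 3 * se)
  expect_lt(abs(mean(lke) - log(th$typical$ke)), 3 * th$omegas[["ke"]] / 100)
})

test_that("cohort covariate frequencies match the demographics", {
  demo <- demographics()
  th <- population_parameters(omegas = c(ke = 0.25)) # lighter sampling
  n <- 100000
  cohort <- sample_cohort(th, demo, n, seed = 5)
  for (g in names(demo$vkorc1_freqs)) {
    p <- demo$vkorc1_freqs[[g]]
    phat <- mean(cohort$covariates$vkorc1 == g)
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  }
  for (g in names(demo$cyp2c9_freqs)) {
    p <- demo$cyp2c9_freqs[[g]]
    phat <- mean(cohort$covariates$cyp2c9 == g)
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  }
  expect_true(all(cohort$covariates$age >= 18 & cohort$covariates$age <= 100))
})

test_that("degenerate demographics give a homogeneous cohort", {
  demo <- demographics(cyp2c9_freqs = c("*1*1" = 0, "*1*2" = 1, "*1*3" = 0,
                                        "*2*2" = 0, "*2*3" = 0, "*3*3" = 0),
                       vkorc1_freqs = c(GG = 0, GA = 0, AA = 1))
  cohort <- sample_cohort(population_parameters(), demo, 50, seed = 1)
  expect_true(all(cohort$covariates$cyp2c9 == "*1*2"))
  expect_true(all(cohort$covariates$vkorc1 == "AA"))
  expect_equal(nrow(cohort$covariates), 50)
})

test_that("pooled moments realise the covariate-weighted mixture", {
  # marginalising over covariates: E[log ke] pooled equals the
  # frequency-weighted mean of the per-genotype means
  th <- population_parameters()
  demo <- demographics(age_sd = 0) # fix age so only genotypes mix
  n <- 40000
  cohort <- sample_cohort(th, demo, n, seed = 11)
  lke <- log(vapply(cohort$parameters, function(p) p$ke, 0))
  per_geno <- vapply(names(demo$cyp2c9_freqs), function(g)
    log(typical_parameters(th, covariate_profile(g, "GG", 65))$ke), 0)
  expected <- sum(unlist(demo$cyp2c9_freqs) * per_geno)
  se <- sd(lke) / sqrt(n)
  expect_lt(abs(mean(lke) - expected), 4 * se)
})

test_that("every sampled parameter set satisfies the invariants", {
  th <- population_parameters()
  demo <- demographics()
  cohort <- sample_cohort(th, demo, 500, seed = 13)
  for (psi in cohort$parameters)
    expect_silent(mipdtrial:::validate_parameters(psi))
})

test_that("invalid demographics are rejected", {
  expect_error(demographics(vkorc1_freqs = c(GG = 0.5, GA = 0.4, AA = 0.2)),
               "sum to 1")
})
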