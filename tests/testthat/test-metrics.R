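test_that("TTR counts measurements inside the inclusive range", {
  rng <- therapeutic_range()
  expect_equal(ttr(c(2, 2.5, 3), rng), 1)
  expect_equal(ttr(c(1, 3.5, 4), rng), 0)
  series <- c(1.2, 1.5, 1.8, 2.0, 2.1, 2.2, 3.3, 2.3, 2.4, 2.5, 3.6, 2.6,
              2.7, 3.1, 2.8, 2.9, 1.9, 3.8, 3.4)
  expect_equal(sum(series >= 2 & series <= 3), 10)
  expect_equal(ttr(series, rng), 10 / 19)
  expect_error(ttr(numeric(0), rng), "non-empty")
})

test_that("single-patient summaries are exact", {
  cov <- tibble::tibble(patient_id = 1L, cyp2c9 = "*1*1", vkorc1 = "GG",
                        age = 71L)
  m <- tibble::tibble(patient_id = 1L, observable = "INR",
                      time_h = 24 * (0:18), value = rep(2.5, 19))
  d <- trial_dataset(m, tibble::tibble(patient_id = 1L, time_h = 0,
                                       dose_mg = 5), cov)
  out <- summarise_trial(d)
  expect_equal(out$patients$maintenance_inr, 2.5)
  expect_equal(out$patients$peak_inr, 2.5)
  expect_equal(out$patients$ttr, 1)
  expect_true(out$patients$success)
  # peak above range with an in-range ending is still a success
  m$value <- c(rep(2.5, 9), 4, rep(2.5, 9))
  out2 <- summarise_trial(trial_dataset(m, d$doses, cov))
  expect_equal(out2$patients$peak_inr, 4)
  expect_true(out2$patients$success)
})

test_that("three-patient toy table matches the hand computation", {
  cov <- tibble::tibble(patient_id = 1:3, cyp2c9 = "*1*1", vkorc1 = "GG",
                        age = 71L)
  m <- tibble::tibble(
    patient_id = rep(1:3, each = 3), observable = "INR",
    time_h = rep(24 * (0:2), 3),
    value = c(1.5, 2.5, 2.2,   # p1: ends in range, ttr 2/3
              3.5, 2.9, 3.8,   # p2: ends out, peak 3.8, ttr 1/3
              2.1, 2.2, 2.3))  # p3: all in range
  d <- trial_dataset(m, tibble::tibble(patient_id = 1:3, time_h = 0,
                                       dose_mg = 5), cov)
  out <- summarise_trial(d)
  expect_equal(out$patients$maintenance_inr, c(2.2, 3.8, 2.3))
  expect_equal(out$patients$peak_inr, c(2.5, 3.8, 2.3))
  expect_equal(out$patients$ttr, c(2 / 3, 1 / 3, 1))
  expect_equal(out$patients$success, c(TRUE, FALSE, TRUE))
  expect_equal(out$success_rate, 2 / 3)
  # consistency: success rate equals the mean of the indicators
  expect_equal(out$success_rate, mean(out$patients$success))
})

test_that("patients without INR rows are excluded with a warning", {
  cov <- tibble::tibble(patient_id = 1:2, cyp2c9 = "*1*1", vkorc1 = "GG",
                        age = 71L)
  m <- tibble::tibble(patient_id = 1L, observable = "INR", time_h = 0,
                      value = 2.5)
  d <- trial_dataset(m, tibble::tibble(patient_id = 1L, time_h = 0,
                                       dose_mg = 5), cov)
  expect_warning(out <- summarise_trial(d), "without INR rows")
  expect_equal(nrow(out$patients), 1)
})

test_that("datasets round-trip bit-exactly through CSV", {
  d <- run_phase1(n = 10, seed = 61)
  path <- tempfile()
  write_dataset(d, path)
  d2 <- read_dataset(path)
  expect_identical(d$measurements$value, d2$measurements$value)
  expect_identical(d$measurements$time_h, d2$measurements$time_h)
  expect_identical(d$covariates, d2$covariates)
  expect_identical(d$doses$dose_mg, d2$doses$dose_mg)
})

test_that("schema violations are reported, extras preserved with a warning", {
  d <- run_phase1(n = 5, seed = 62)
  path <- tempfile()
  write_dataset(d, path)
  cov <- utils::read.csv(file.path(path, "covariates.csv"))
  cov$CYP2C9 <- NULL
  utils::write.csv(cov, file.path(path, "covariates.csv"), row.names = FALSE)
  expect_error(read_dataset(path), "CYP2C9")
  write_dataset(d, path)
  meas <- utils::read.csv(file.path(path, "measurements.csv"))
  meas$Batch <- "A"
  utils::write.csv(meas, file.path(path, "measurements.csv"),
                   row.names = FALSE)
  expect_warning(d3 <- read_dataset(path), "Batch")
  expect_true("Batch" %in% names(d3$measurements))
  path2 <- tempfile()
  write_dataset(d3, path2)
  expect_true("Batch" %in% names(utils::read.csv(
    file.path(path2, "measurements.csv"))))
})

test_that("metrics are agent-agnostic", {
  d <- run_mipd_trial(agent = zero_dose_agent(), n = 4, seed = 9)
  d$metadata$agent <- "renamed"
  expect_identical(summarise_trial(d)$patients,
                   summarise_trial(d)$patients)
})

test_that("config round-trips through JSON", {
  cfg <- ct_config(y_star = 2.5, dose_max = 25,
                   iov = iov_config(sigma_eta = 0.2))
  p <- tempfile(fileext = ".json")
  write_config(cfg, p)
  cfg2 <- read_config(p)
  expect_equal(cfg2$iov$sigma_eta, 0.2)
  expect_equal(cfg2$dose_max, 25)
  expect_equal(unclass(cfg2$population$typical),
               unclass(cfg$population$typical))
})
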