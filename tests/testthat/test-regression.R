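test_that("training refuses insufficient data", {
  df <- data.frame(cyp2c9 = "*1*1", vkorc1 = "GG", age = 50, inr = 2.5,
                   dose = 5)[rep(1, 20), ]
  expect_error(train_regression(df), "insufficient training data")
})

test_that("network recovers a known linear dose function", {
  set.seed(10)
  n <- 600
  df <- data.frame(cyp2c9 = sample(c("*1*1", "*1*2"), n, TRUE),
                   vkorc1 = sample(c("GG", "GA"), n, TRUE),
                   age = sample(30:90, n, TRUE))
  df$inr <- 2.5
  df$dose <- 2 + 0.1 * df$age
  hold <- df[1:100, ]
  model <- train_regression(df[101:n, ], epochs = 60, patience = 60,
                            seed = 11)
  pred <- vapply(seq_len(nrow(hold)), function(i)
    predict_maintenance_dose(model,
                             covariate_profile(hold$cyp2c9[i],
                                               hold$vkorc1[i], hold$age[i]),
                             2.5), 0)
  rmse <- sqrt(mean((pred - hold$dose)^2))
  expect_lt(rmse, 0.1 * sd(df$dose))
  # pointwise recovery at covariate means
  mid <- predict_maintenance_dose(model, covariate_profile("*1*1", "GG", 60),
                                  2.5)
  expect_lt(abs(mid - 8) / 8, 0.1)
})

test_that("training loss trends downward and is logged", {
  set.seed(12)
  n <- 200
  df <- data.frame(cyp2c9 = "*1*1", vkorc1 = "GG", age = sample(30:90, n, TRUE))
  df$inr <- 2.5
  df$dose <- 2 + 0.1 * df$age
  model <- train_regression(df, epochs = 40, patience = 40, seed = 13)
  h <- model$history
  expect_gt(nrow(h), 10)
  # smoothed loss over the first vs last third
  k <- floor(nrow(h) / 3)
  expect_lt(mean(h$train[(nrow(h) - k + 1):nrow(h)]), mean(h$train[1:k]))
})

test_that("duplicated rows leave fitted predictions unchanged", {
  set.seed(14)
  n <- 100
  df <- data.frame(cyp2c9 = "*1*1", vkorc1 = "GG", age = sample(30:90, n, TRUE))
  df$inr <- 2.5
  df$dose <- 2 + 0.1 * df$age
  m1 <- train_regression(df, epochs = 15, patience = 15, seed = 15)
  m2 <- train_regression(rbind(df, df), epochs = 15, patience = 15, seed = 15)
  p1 <- predict_maintenance_dose(m1, covariate_profile("*1*1", "GG", 60), 2.5)
  p2 <- predict_maintenance_dose(m2, covariate_profile("*1*1", "GG", 60), 2.5)
  # same information content: predictions agree to within the dose step
  expect_lt(abs(p1 - p2), 1.01)
})

test_that("predictions are bounded, rounded, and identical for identical covariates", {
  set.seed(16)
  n <- 120
  df <- data.frame(cyp2c9 = sample(c("*1*1", "*1*3"), n, TRUE),
                   vkorc1 = "GG", age = sample(30:90, n, TRUE))
  df$inr <- runif(n, 1.5, 3.5)
  df$dose <- pmin(30, pmax(0, 15 - 3 * (df$cyp2c9 == "*1*3")))
  model <- train_regression(df, epochs = 10, patience = 10, seed = 17)
  for (a in c(20, 50, 95)) {
    d <- predict_maintenance_dose(model, covariate_profile("*1*3", "GG", a),
                                  2.5)
    expect_gte(d, 0); expect_lte(d, 30)
    expect_equal(d %% 0.5, 0)
  }
  chi <- covariate_profile("*1*1", "GG", 44)
  expect_identical(predict_maintenance_dose(model, chi, 2.5),
                   predict_maintenance_dose(model, chi, 2.5))
  # the agent adapter ignores the monitoring record: constant daily dose
  agent <- regression_agent(model)
  rec_a <- monitoring_record(tibble::tibble(time_h = 0, value = 1.1))
  rec_b <- monitoring_record(tibble::tibble(time_h = 0, value = 4.9))
  expect_identical(agent$next_dose(chi, rec_a, 2.5, 0),
                   agent$next_dose(chi, rec_b, 2.5, 7))
})

test_that("untrained or wrong inputs raise errors", {
  expect_error(predict_maintenance_dose(list(), covariate_profile(), 2.5),
               "trained regression_model")
})

test_that("regression models round-trip through JSON", {
  set.seed(18)
  n <- 80
  df <- data.frame(cyp2c9 = "*1*1", vkorc1 = "GG", age = sample(30:90, n, TRUE))
  df$inr <- 2.5; df$dose <- 2 + 0.1 * df$age
  m <- train_regression(df, epochs = 5, patience = 5, seed = 19)
  p <- tempfile(fileext = ".json")
  write_regression_model(m, p)
  m2 <- read_regression_model(p)
  chi <- covariate_profile("*1*1", "GG", 70)
  expect_equal(predict_maintenance_dose(m, chi, 2.5),
               predict_maintenance_dose(m2, chi, 2.5))
})
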