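#' Train the maintenance-dose regression network
#'
#' MIPD method 1: a feed-forward network regressing the daily maintenance
#' dose on the patient's covariates and the achieved INR. The architecture is
#' three fully connected layers -- two hidden layers of width 1024 with ReLU
#' activations and a sigmoid output scaled to `[0, dose_max]` -- trained to
#' minimise mean squared error with Adam. Training uses the measured
#' end-of-trial INR as the response feature, so that prediction can
#' substitute the target INR `y*`.
#'
#' @param phase3 A phase III [trial_dataset()] (one INR row and one
#'   maintenance-dose row per patient), or a data frame with columns
#'   `cyp2c9`, `vkorc1`, `age`, `inr`, `dose`.
#' @param epochs,batch_size,lr Optimiser settings (Adam).
#' @param val_fraction Fraction of rows held out for validation.
#' @param patience Early-stopping patience in epochs (on validation loss).
#' @param hidden Width of the two hidden layers.
#' @param dose_max Output scale in mg.
#' @param dose_step Rounding granularity used at prediction time.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return A `regression_model` with the fitted network, feature scalers and
#'   the training/validation loss history.
#' @export
train_regression <- function(phase3, epochs = 500, batch_size = 64, lr = 1e-4,
                             val_fraction = 0.1, patience = 50, hidden = 1024,
                             dose_max = 30, dose_step = 0.5, seed = 1) {
  df <- regression_training_frame(phase3)
  if (nrow(df) < 50)
    stop(sprintf("insufficient training data: %d rows (< 50)", nrow(df)),
         call. = FALSE)
  with_seed(seed, {
    sc <- list(age_center = mean(df$age), age_scale = max(sd(df$age), 1e-8),
               inr_center = mean(df$inr), inr_scale = max(sd(df$inr), 1e-8),
               dose_max = dose_max, dose_step = dose_step)
    X <- cbind(encode_covariates(df$cyp2c9, df$vkorc1, df$age,
                                 sc$age_center, sc$age_scale),
               (df$inr - sc$inr_center) / sc$inr_scale)
    # train on the normalised dose scale (sigmoid output in [0, 1]); keeps
    # gradients through the saturating output well-conditioned
    y <- matrix(df$dose / dose_max, ncol = 1)
    n <- nrow(X)
    n_val <- max(1, round(val_fraction * n))
    idx <- sample(n)
    val <- idx[seq_len(n_val)]
    trn <- idx[-seq_len(n_val)]
    net <- mlp_init(c(11, hidden, hidden, 1), out_activation = "sigmoid",
                    out_scale = 1)
    opt <- adam_init(net)
    best <- list(net = net, loss = Inf, epoch = 0)
    hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
    for (ep in seq_len(epochs)) {
      ord <- sample(trn)
      tl <- 0
      for (start in seq(1, length(ord), by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1, length(ord))]
        A <- mlp_forward(net, X[bi, , drop = FALSE])
        err <- A[[length(A)]] - y[bi, , drop = FALSE]
        tl <- tl + sum(err^2)
        g <- mlp_backward(net, A, 2 * err / length(bi))
        st <- adam_step(net, opt, g, lr = lr)
        net <- st$net; opt <- st$opt
      }
      vl <- mean((mlp_predict(net, X[val, , drop = FALSE]) -
                    y[val, , drop = FALSE])^2)
      # history reported in mg^2
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train = dose_max^2 * tl / length(trn),
                                     val = dose_max^2 * vl))
      if (vl < best$loss) best <- list(net = net, loss = vl, epoch = ep)
      if (ep - best$epoch >= patience) break
    }
    structure(list(net = best$net, scalers = sc, history = hist, seed = seed),
              class = "regression_model")
  })
}

regression_training_frame <- function(phase3) {
  if (inherits(phase3, "trial_dataset")) {
    inr <- phase3$measurements[phase3$measurements$observable == "INR", ]
    last_inr <- do.call(rbind, lapply(split(inr, inr$patient_id), function(s)
      data.frame(patient_id = s$patient_id[1],
                 inr = s$value[which.max(s$time_h)])))
    d <- phase3$doses
    last_dose <- do.call(rbind, lapply(split(d, d$patient_id), function(s)
      data.frame(patient_id = s$patient_id[1],
                 dose = s$dose_mg[which.max(s$time_h)])))
    df <- merge(merge(phase3$covariates, last_inr, by = "patient_id"),
                last_dose, by = "patient_id")
    df
  } else {
    df <- as.data.frame(phase3)
    need <- c("cyp2c9", "vkorc1", "age", "inr", "dose")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("training frame is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    df
  }
}

#' Predict a maintenance dose from covariates and target INR
#'
#' The fitted network evaluated at the patient's covariates with the target
#' INR substituted for the response feature. The prediction is static: the
#' same dose is returned for every day of a trial, with no use of monitoring
#' data.
#'
#' @param model A `regression_model` from [train_regression()].
#' @param chi A [covariate_profile()].
#' @param y_star Target INR.
#' @return Dose in mg, in `[0, dose_max]`, rounded to the trial granularity.
#' @export
predict_maintenance_dose <- function(model, chi, y_star = 2.5) {
  if (!inherits(model, "regression_model"))
    stop("model must be a trained regression_model", call. = FALSE)
  sc <- model$scalers
  x <- cbind(encode_covariates(chi$cyp2c9, chi$vkorc1, chi$age,
                               sc$age_center, sc$age_scale),
             (y_star - sc$inr_center) / sc$inr_scale)
  d <- sc$dose_max * mlp_predict(model$net, x)[1, 1]
  min(sc$dose_max, max(0, round(d / sc$dose_step) * sc$dose_step))
}

#' Dosing agent wrapping the regression model
#'
#' Ignores the monitoring record entirely (a static, covariate-only policy):
#' all 19 trial doses of a patient are identical.
#'
#' @param model A `regression_model`.
#' @return A [dosing_agent()].
#' @export
regression_agent <- function(model) {
  dosing_agent("regression", function(chi, record, y_star, day)
    predict_maintenance_dose(model, chi, y_star))
}

#' Serialise / restore a regression model as JSON
#'
#' @param model A `regression_model`.
#' @param path File path (`.json`).
#' @return `write_regression_model` returns `path` invisibly;
#'   `read_regression_model` the model.
#' @export
write_regression_model <- function(model, path) {
  x <- list(sizes = model$net$sizes,
            W = lapply(model$net$W, identity),
            b = model$net$b,
            out_activation = model$net$out_activation,
            out_scale = model$net$out_scale,
            scalers = model$scalers, seed = model$seed)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_regression_model
#' @export
read_regression_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- list(sizes = x$sizes, W = x$W,
              b = lapply(x$b, as.numeric),
              out_activation = x$out_activation, out_scale = x$out_scale)
  structure(list(net = net, scalers = x$scalers, history = NULL,
                 seed = x$seed),
            class = "regression_model")
}
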