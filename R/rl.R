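#' Discrete dose grid of the RL agent
#'
#' 58 doses from 0 to 28.5 mg in 0.5 mg steps, matching the Q-network output
#' width.
#'
#' @return Ascending numeric vector of length 58 including 0.
#' @export
dose_grid <- function() seq(0, 28.5, by = 0.5)

# fixed feature scalers of the RL state: [scaled INR, one-hot CYP2C9 (6),
# one-hot VKORC1 (3), standardised age]; constants chosen once from the
# default demographics and the therapeutic target, not fitted
RL_INR_CENTER <- 2.5
RL_INR_SCALE <- 1.5
RL_AGE_CENTER <- 65
RL_AGE_SCALE <- 10

rl_features <- function(inr, chi) {
  if (any(inr <= 0)) stop("INR state must be > 0", call. = FALSE)
  cbind((inr - RL_INR_CENTER) / RL_INR_SCALE,
        encode_covariates(rep(chi$cyp2c9, length(inr)),
                          rep(chi$vkorc1, length(inr)),
                          rep(chi$age, length(inr)),
                          RL_AGE_CENTER, RL_AGE_SCALE))
}

#' Initialise a Q-network
#'
#' Input (11 state features) -> 256 -> 128 -> 64 hidden ReLU layers -> linear
#' output of width 58 (one Q-value per grid dose).
#'
#' @param seed Integer seed for the weight initialisation.
#' @return An MLP object usable with [select_dose()] and [policy_slice()].
#' @export
q_network <- function(seed = 1) mlp_init(c(11, 256, 128, 64, 58), seed = seed)

#' Epsilon-greedy dose selection
#'
#' With probability `1 - epsilon` the dose with the maximum Q-value (ties
#' broken towards the lowest dose); otherwise a uniform draw over the grid.
#'
#' @param net A Q-network.
#' @param state Feature row vector (from the latest INR and covariates).
#' @param epsilon Exploration probability in `[0, 1]`.
#' @param grid The [dose_grid()].
#' @param seed Optional integer seed.
#' @return List with `action` (1-based index into the grid) and `dose` (mg).
#' @export
select_dose <- function(net, state, epsilon = 0, grid = dose_grid(),
                        seed = NULL) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  with_seed(seed, {
    a <- if (epsilon > 0 && stats::runif(1) < epsilon) {
      sample.int(length(grid), 1)
    } else {
      q <- mlp_predict(net, matrix(state, nrow = 1))[1, ]
      which.max(q >= max(q)) # first (lowest-dose) maximiser
    }
    list(action = a, dose = grid[a])
  })
}

#' Double Q-learning regression targets
#'
#' `y = r + discount * Q_target(s', argmax_a Q_online(s', a))` for
#' non-terminal transitions and `y = r` for terminal ones: the online network
#' selects the action, the target network evaluates it.
#'
#' @param batch List with `state`, `next_state` (matrices), `action`
#'   (integer), `reward` (numeric), `terminal` (logical).
#' @param online,target Q-networks of identical architecture.
#' @param discount Discount factor in `[0, 1]`.
#' @return Numeric vector of per-transition targets.
#' @export
td_target <- function(batch, online, target, discount = 0.99) {
  y <- batch$reward
  live <- !batch$terminal
  if (any(live)) {
    ns <- batch$next_state[live, , drop = FALSE]
    q_on <- mlp_predict(online, ns)
    a_star <- max.col(q_on, ties.method = "first")
    q_tg <- mlp_predict(target, ns)
    y[live] <- y[live] + discount * q_tg[cbind(seq_len(nrow(ns)), a_star)]
  }
  y
}

#' Reward of the RL agent
#'
#' Negative absolute deviation of the next-day INR from the target: maximal
#' (zero) exactly on target.
#'
#' @param inr_next Next-day INR measurement.
#' @param y_star Target INR.
#' @return Reward (<= 0).
#' @export
rl_reward <- function(inr_next, y_star = 2.5) -abs(inr_next - y_star)

#' Train the Deep RL agent online against a PKPD treatment-response emulator
#'
#' Episodic Double-DQN training: each episode treats one virtual patient
#' drawn from the emulator's population for `horizon` days; the agent sees a
#' noisy INR measurement each morning (the emulator applies the measurement
#' layer but no execution delays), selects a grid dose epsilon-greedily,
#' and receives reward `-|INR_next - y_star|`. Transitions feed a replay
#' buffer; minibatch Adam updates minimise the Double Q-learning temporal
#' difference error, with a periodically synchronised target network and a
#' linear epsilon decay over the first 80\% of episodes.
#'
#' @param emulator An emulator from [ct_emulator()] or [posterior_emulator()].
#' @param episodes Number of training episodes (virtual patients).
#' @param horizon Episode length in days.
#' @param y_star Target INR, fixed before training.
#' @param discount Discount factor.
#' @param buffer_size,batch_size Replay-buffer settings.
#' @param lr Adam learning rate.
#' @param sync_every Gradient steps between target-network synchronisations.
#' @param eps_start,eps_end Epsilon-greedy schedule endpoints.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An `rl_model`: list with the trained `net`, the `grid`, training
#'   `history` (per-episode return and epsilon) and settings.
#' @export
train_rl_agent <- function(emulator, episodes = 2000, horizon = 19,
                           y_star = 2.5, discount = 0.99,
                           buffer_size = 50000, batch_size = 64, lr = 1e-4,
                           sync_every = 500, eps_start = 1.0, eps_end = 0.05,
                           seed = 1) {
  with_seed(seed, {
    grid <- dose_grid()
    net <- mlp_init(c(11, 256, 128, 64, 58))
    target <- net
    opt <- adam_init(net)
    nf <- 11
    buf_s <- matrix(0, buffer_size, nf); buf_ns <- matrix(0, buffer_size, nf)
    buf_a <- integer(buffer_size); buf_r <- numeric(buffer_size)
    buf_term <- logical(buffer_size)
    n_buf <- 0; pos <- 0; steps <- 0
    returns <- numeric(episodes); eps_hist <- numeric(episodes)
    decay_until <- max(1, floor(0.8 * episodes))
    for (ep in seq_len(episodes)) {
      eps <- if (ep >= decay_until) eps_end
        else eps_start + (eps_end - eps_start) * (ep - 1) / (decay_until - 1)
      eps_hist[ep] <- eps
      pat <- emulator$sample_patient()
      st <- tryCatch({
        state <- emulator$reset(pat$psi)
        y <- emulator$observe(state, pat$psi)
        s <- rl_features(y, pat$chi)[1, ]
        ret <- 0
        for (t in seq_len(horizon)) {
          act <- select_dose(net, s, epsilon = eps, grid = grid)
          state <- emulator$step(state, pat$psi, 24 * (t - 1), act$dose)
          y <- emulator$observe(state, pat$psi)
          r <- rl_reward(y, y_star)
          ret <- ret + r
          s2 <- rl_features(y, pat$chi)[1, ]
          pos <- pos %% buffer_size + 1
          n_buf <- min(n_buf + 1, buffer_size)
          buf_s[pos, ] <- s; buf_ns[pos, ] <- s2
          buf_a[pos] <- act$action; buf_r[pos] <- r
          buf_term[pos] <- (t == horizon)
          s <- s2
          if (n_buf >= batch_size) {
            bi <- sample.int(n_buf, batch_size)
            batch <- list(state = buf_s[bi, , drop = FALSE],
                          next_state = buf_ns[bi, , drop = FALSE],
                          action = buf_a[bi], reward = buf_r[bi],
                          terminal = buf_term[bi])
            tgt <- td_target(batch, net, target, discount)
            A <- mlp_forward(net, batch$state)
            Q <- A[[length(A)]]
            if (max(abs(Q)) > 1e4)
              stop("Q-values diverged (|Q| > 1e4); aborting training",
                   call. = FALSE)
            sel <- cbind(seq_len(batch_size), batch$action)
            dOut <- matrix(0, batch_size, ncol(Q))
            dOut[sel] <- 2 * (Q[sel] - tgt) / batch_size
            g <- mlp_backward(net, A, dOut)
            upd <- adam_step(net, opt, g, lr = lr)
            net <- upd$net; opt <- upd$opt
            steps <- steps + 1
            if (steps %% sync_every == 0) target <- net
          }
        }
        ret
      }, mipdtrial_emulator_error = function(e) {
        warning(sprintf("episode %d discarded: %s", ep, conditionMessage(e)),
                call. = FALSE)
        NA_real_
      })
      returns[ep] <- st
    }
    structure(list(net = net, grid = grid, y_star = y_star,
                   history = data.frame(episode = seq_len(episodes),
                                        return_ = returns,
                                        epsilon = eps_hist),
                   settings = list(episodes = episodes, horizon = horizon,
                                   discount = discount, lr = lr,
                                   sync_every = sync_every, seed = seed)),
              class = "rl_model")
  })
}

#' Greedy policy slice over an INR grid
#'
#' The dose the trained policy would administer at each INR value for a fixed
#' covariate profile; the diagnostic view of the learned dose function.
#'
#' @param model An `rl_model` (or a bare Q-network).
#' @param chi A [covariate_profile()].
#' @param inr_grid Numeric vector of INR values (> 0).
#' @return Numeric vector of doses (mg), one per grid value.
#' @export
policy_slice <- function(model, chi, inr_grid = seq(0.5, 7, by = 0.1)) {
  net <- if (inherits(model, "rl_model")) model$net else model
  grid <- if (inherits(model, "rl_model")) model$grid else dose_grid()
  X <- rl_features(inr_grid, chi)
  q <- mlp_predict(net, X)
  grid[max.col(q, ties.method = "first")]
}

#' Dosing agent wrapping the trained RL policy
#'
#' Uses only the most recent INR measurement in the monitoring record plus
#' the covariates (the Markov state of the Q-network), acting greedily.
#'
#' @param model An `rl_model` from [train_rl_agent()].
#' @return A [dosing_agent()].
#' @export
rl_agent <- function(model) {
  stopifnot(inherits(model, "rl_model"))
  dosing_agent("deep-rl", function(chi, record, y_star, day) {
    m <- record$measurements
    if (nrow(m) == 0)
      stop("RL agent requires at least one INR measurement", call. = FALSE)
    y <- m$value[nrow(m)]
    select_dose(model$net, rl_features(y, chi)[1, ], epsilon = 0,
                grid = model$grid)$dose
  })
}

#' Serialise / restore an RL model as JSON
#'
#' @param model An `rl_model`.
#' @param path File path (`.json`).
#' @return `write_rl_model` returns `path` invisibly; `read_rl_model` the
#'   model.
#' @export
write_rl_model <- function(model, path) {
  x <- list(sizes = model$net$sizes, W = model$net$W, b = model$net$b,
            out_activation = model$net$out_activation,
            out_scale = model$net$out_scale,
            grid = model$grid, y_star = model$y_star,
            settings = model$settings)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rl_model
#' @export
read_rl_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- list(sizes = x$sizes, W = x$W, b = lapply(x$b, as.numeric),
              out_activation = x$out_activation, out_scale = x$out_scale)
  structure(list(net = net, grid = x$grid, y_star = x$y_star,
                 history = NULL, settings = x$settings),
            class = "rl_model")
}
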