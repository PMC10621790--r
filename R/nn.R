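# Minimal dense feed-forward network with ReLU hidden layers and Adam,
# implemented with base matrix algebra. Shared by the maintenance-dose
# regression agent and the Q-network of the reinforcement-learning agent.
# Rows of the input matrix are samples.

mlp_init <- function(sizes, out_activation = c("linear", "sigmoid"),
                     out_scale = 1, seed = NULL) {
  out_activation <- match.arg(out_activation)
  with_seed(seed, {
    L <- length(sizes) - 1
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      # He initialisation for the ReLU layers, Xavier for the output layer
      sd_l <- if (l < L) sqrt(2 / sizes[l]) else sqrt(1 / sizes[l])
      W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = sd_l),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
    list(sizes = sizes, W = W, b = b, out_activation = out_activation,
         out_scale = out_scale)
  })
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1]] <- if (l < L) pmax(Z, 0)
      else if (net$out_activation == "sigmoid")
        net$out_scale / (1 + exp(-Z))
      else Z
  }
  A
}

mlp_predict <- function(net, X) {
  A <- mlp_forward(net, X)
  A[[length(A)]]
}

# backpropagate an upstream gradient dOut (same shape as the output layer)
mlp_backward <- function(net, A, dOut) {
  L <- length(net$W)
  out <- A[[L + 1]]
  delta <- if (net$out_activation == "sigmoid") {
    s <- out / net$out_scale
    dOut * net$out_scale * s * (1 - s)
  } else dOut
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(net$W[[l]])) * (A[[l]] > 0)
  }
  list(W = gW, b = gb)
}

adam_init <- function(net) {
  z <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x))
  list(mW = lapply(net$W, z), vW = lapply(net$W, z),
       mb = lapply(net$b, z), vb = lapply(net$b, z), t = 0)
}

adam_step <- function(net, opt, grads, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * grads$W[[l]]
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (opt$mW[[l]] / bc1) /
      (sqrt(opt$vW[[l]] / bc2) + eps)
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * grads$b[[l]]
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (opt$mb[[l]] / bc1) /
      (sqrt(opt$vb[[l]] / bc2) + eps)
  }
  list(net = net, opt = opt)
}

# one-hot covariate encoding shared by both neural agents: CYP2C9 (6),
# VKORC1 (3), then standardised age
encode_covariates <- function(cyp2c9, vkorc1, age, age_center, age_scale) {
  n <- length(age)
  X <- matrix(0, n, 10)
  X[cbind(seq_len(n), match(cyp2c9, CYP2C9_LEVELS))] <- 1
  X[cbind(seq_len(n), 6 + match(vkorc1, VKORC1_LEVELS))] <- 1
  X[, 10] <- (age - age_center) / age_scale
  X
}
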