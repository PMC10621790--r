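# Compact covariance matrix adaptation evolution strategy (CMA-ES),
# (mu/mu_w, lambda) with rank-one and rank-mu covariance updates and
# cumulative step-size adaptation. Box constraints are handled by repairing
# candidates onto the box before evaluation. Used for dosing-regimen
# optimisation; small dimensions (<= 19), so the per-iteration eigen
# decomposition is cheap.

cma_es <- function(fn, x0, sigma0, lower = -Inf, upper = Inf,
                   popsize = NULL, max_iter = 200, tol_fun = 1e-3,
                   patience = 25) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  lambda <- if (is.null(popsize)) 4 + floor(3 * log(n)) else popsize
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- pmin(pmax(x0, lower), upper)
  sigma <- sigma0
  pc <- ps <- rep(0, n)
  C <- diag(n); B <- diag(n); D <- rep(1, n)
  repair <- function(x) pmin(pmax(x, lower), upper)
  best <- list(par = repair(x0), value = fn(repair(x0)))
  zero_try <- repair(rep(0, n))
  f0 <- fn(zero_try)
  if (f0 < best$value) best <- list(par = zero_try, value = f0)
  last_improve <- 0; iters <- 0
  for (it in seq_len(max_iter)) {
    iters <- it
    arz <- matrix(stats::rnorm(n * lambda), n, lambda)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    arfit <- numeric(lambda)
    for (k in seq_len(lambda)) {
      xr <- repair(arx[, k])
      arfit[k] <- fn(xr)
      if (arfit[k] < best$value - tol_fun) last_improve <- it
      if (arfit[k] < best$value) best <- list(par = xr, value = arfit[k])
    }
    ord <- order(arfit)[seq_len(mu)]
    ymean <- as.vector(ary[, ord, drop = FALSE] %*% w)
    xmean <- xmean + sigma * ymean
    zmean <- as.vector(arz[, ord, drop = FALSE] %*% w)
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) *
      as.vector(B %*% zmean)
    hsig <- as.numeric(sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * it)) / chiN < 1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean
    artmp <- ary[, ord, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    eg <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eg$values, 1e-20))
    B <- eg$vectors
    if (it - last_improve >= patience) break
  }
  best$iterations <- iters
  best$converged <- iters < max_iter
  best
}
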