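# Covariance-matrix-adaptation evolution strategy ((mu/mu_w, lambda)-CMA-ES),
# the minimizer used for every fitting and design task in this package.
# Standard strategy parameters (rank-mu update, cumulation paths, step-size
# control via the conjugate evolution path).  Box constraints are handled by
# evaluating the objective at the projection onto the box and adding a
# quadratic penalty on the excursion, which keeps the sampling distribution
# unconstrained while making out-of-box optima unattractive.

#' Minimize a function with CMA-ES
#'
#' @param fn objective function of a numeric vector, returning a scalar.
#' @param x0 numeric start vector.
#' @param sigma0 initial global step size (same scale as `x0`).
#' @param lower,upper box bounds (recycled to `length(x0)`).
#' @param maxiter maximum number of generations.
#' @param lambda population size; default `4 + floor(3 * log(n))`.
#' @param seed integer seed; the run is fully reproducible given it.
#' @param stop_fitness stop early once the best objective falls below this.
#' @param boundary_penalty weight of the quadratic out-of-box penalty.
#' @return a list with elements `par` (best point, inside the box), `value`
#'   (its objective), `counteval`, `trace` (best objective per generation)
#'   and `converged` (`TRUE` when `stop_fitness` was reached).
#' @export
cma_es <- function(fn, x0, sigma0, lower = -Inf, upper = Inf,
                   maxiter = 200L, lambda = NULL, seed = 42L,
                   stop_fitness = -Inf, boundary_penalty = 1e4) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  set.seed(as.integer(seed))
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu)); w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- as.numeric(x0); sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n); B <- diag(n); D <- rep(1, n)
  eigeneval <- 0L; counteval <- 0L
  best <- list(par = pmin(pmax(xmean, lower), upper), value = Inf)
  trace <- numeric(0)

  for (iter in seq_len(maxiter)) {
    arz <- matrix(stats::rnorm(n * lambda), n, lambda)
    arx <- xmean + sigma * (B %*% (D * arz))
    fit <- numeric(lambda)
    for (k in seq_len(lambda)) {
      xk <- pmin(pmax(arx[, k], lower), upper)
      fit[k] <- fn(xk) + boundary_penalty * sum((arx[, k] - xk)^2)
      counteval <- counteval + 1L
      if (fit[k] < best$value) best <- list(par = xk, value = fit[k])
    }
    ord <- order(fit)
    xold <- xmean
    xmean <- drop(arx[, ord[seq_len(mu)], drop = FALSE] %*% w)
    ymean <- (xmean - xold) / sigma
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * drop(B %*% ((1 / D) * crossprod(B, ymean)))
    hsig <- sum(ps^2) / (1 - (1 - cs)^(2 * counteval / lambda)) / n <
      2 + 4 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean
    arymu <- (arx[, ord[seq_len(mu)], drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * arymu %*% (w * t(arymu))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    if (counteval - eigeneval > lambda / (c1 + cmu) / n / 10) {
      eigeneval <- counteval
      C <- (C + t(C)) / 2
      e <- eigen(C, symmetric = TRUE)
      B <- e$vectors; D <- sqrt(pmax(e$values, 1e-20))
    }
    trace <- c(trace, best$value)
    if (best$value <= stop_fitness) break
  }
  list(par = best$par, value = best$value, counteval = counteval,
       trace = trace, converged = best$value <= stop_fitness)
}
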