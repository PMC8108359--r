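# Independent oracles and small builders shared across tests.

# Brute-force numeric integration of a km_curve step function over (t, Inf),
# divided by S(t): evaluates S on a fine grid instead of using the exact
# knot-based integral in mean_residual_life().
mrl_numeric <- function(curve, t, n_grid = 2e5) {
  s_at <- function(u) {
    vapply(u, function(ui) {
      i <- findInterval(ui, curve$times)
      if (i == 0L) 1 else curve$surv[i]
    }, numeric(1))
  }
  upper <- max(curve$times)
  grid <- seq(t, upper, length.out = n_grid)
  h <- grid[2] - grid[1]
  # midpoint rule; S is piecewise constant so this converges fast
  mids <- grid[-1] - h / 2
  sum(s_at(mids)) * h / s_at(t)
}

# minimal converged glmm_fit for pooling arithmetic tests
make_fit <- function(q, u, coef = "time", n = 100L, p = 3L) {
  structure(list(coefficients = stats::setNames(q, coef),
                 vcov = matrix(u, 1, 1, dimnames = list(coef, coef)),
                 re_variances = c(.olre = 0), loglik = 0,
                 converged = TRUE, n = n, p = p, messages = character()),
            class = "glmm_fit")
}

# one fully observed exponential-ish toy dataset with covariates for MI tests
toy_mi_data <- function(n = 40L, seed = 1L, censoring = TRUE) {
  set.seed(seed)
  x <- stats::rweibull(n, shape = 1.2, scale = 10)
  cns <- if (censoring) stats::rweibull(n, shape = 1.2, scale = 15) else Inf
  d <- data.frame(time = pmin(x, cns), event = x <= cns,
                  z = rep_len(c(0, 1), n))
  tot <- round(stats::runif(n, 500, 2000))
  p <- stats::plogis(-1.5 + 0.5 * d$z + stats::rnorm(n, 0, 0.3))
  d$y <- stats::rbinom(n, tot, p)
  d$n <- tot
  d
}
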