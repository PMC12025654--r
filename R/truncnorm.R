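# Closed-form moments, mgf, and inverse-CDF sampling for the truncated
# normal distribution on [a, b]. Used to calibrate bounded cohort marginals
# (fractal dimension on [1, 2], flow density on [0, 100]) so that the
# *realized* mean and SD after truncation hit their targets exactly.

tnorm_moments <- function(mu, sigma, a, b) {
  alpha <- (a - mu) / sigma
  beta <- (b - mu) / sigma
  z <- stats::pnorm(beta) - stats::pnorm(alpha)
  da <- stats::dnorm(alpha)
  db <- stats::dnorm(beta)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (alpha * da - beta * db) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(v))
}

# E[exp(t X)] for X ~ TN(mu, sigma; a, b)
tnorm_mgf <- function(t, mu, sigma, a, b) {
  alpha <- (a - mu) / sigma
  beta <- (b - mu) / sigma
  z <- stats::pnorm(beta) - stats::pnorm(alpha)
  exp(mu * t + 0.5 * sigma^2 * t^2) *
    (stats::pnorm(beta - sigma * t) - stats::pnorm(alpha - sigma * t)) / z
}

# Find (mu, sigma) of the parent normal such that the [a, b]-truncated
# distribution has the requested mean and SD. Deterministic Nelder-Mead
# refinement of the untruncated start; targets must be attainable (mean
# inside (a, b)).
tnorm_solve <- function(mean_target, sd_target, a, b) {
  stopifnot(mean_target > a, mean_target < b, sd_target > 0)
  obj <- function(par) {
    mo <- tnorm_moments(par[1L], exp(par[2L]), a, b)
    (mo$mean - mean_target)^2 + (mo$sd - sd_target)^2
  }
  fit <- stats::optim(c(mean_target, log(sd_target)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000L))
  mu <- fit$par[1L]
  sigma <- exp(fit$par[2L])
  mo <- tnorm_moments(mu, sigma, a, b)
  if (abs(mo$mean - mean_target) > 1e-6 * max(1, abs(mean_target)) ||
      abs(mo$sd - sd_target) > 1e-6 * max(1, sd_target)) {
    stop("truncated-normal calibration failed to converge", call. = FALSE)
  }
  list(mu = mu, sigma = sigma)
}

rtnorm <- function(n, mu, sigma, a, b) {
  lo <- stats::pnorm((a - mu) / sigma)
  hi <- stats::pnorm((b - mu) / sigma)
  mu + sigma * stats::qnorm(stats::runif(n, lo, hi))
}
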