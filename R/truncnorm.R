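# Truncated-normal machinery for the cohort calibration.
#
# The calibration table stores the printed cohort mean +/- SD for each quantity.
# Sampling from a normal truncated at a physiologic bound shifts both moments,
# so the underlying (mu, sigma) are re-standardised such that the truncated
# distribution reproduces the printed moments; `tn_calibrate()` solves that
# two-equation system numerically.

tn_moments <- function(mu, sigma, lower = -Inf, upper = Inf) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  ada <- if (is.finite(a)) a * da else 0
  bdb <- if (is.finite(b)) b * db else 0
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (ada - bdb) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(v))
}

#' Calibrate a truncated normal to target moments
#'
#' Finds `(mu, sigma)` such that the normal truncated to `[lower, upper]` has
#' the requested mean and standard deviation, so a sampled cohort reproduces a
#' printed summary statistic despite truncation at physiologic bounds.
#'
#' @param mean,sd Target moments of the truncated distribution (`sd > 0`).
#' @param lower,upper Truncation bounds.
#' @return List with `mu`, `sigma`, `lower`, `upper` and the achieved
#'   `mean`/`sd` (matched to ~1e-6 relative error).
#' @export
tn_calibrate <- function(mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  if (is.finite(lower) && mean <= lower)
    stop("target mean must exceed the lower truncation bound")
  if (is.infinite(upper)) {
    # lower truncation only: the truncated sd/(mean - lower) ratio depends on
    # the standardised bound a = (lower - mu)/sigma alone and is monotone in
    # it, so solve 1-D then rescale. The ratio is bounded above by 1
    # (exponential-tail limit), which caps the representable dispersion.
    lam <- function(a) exp(stats::dnorm(a, log = TRUE) -
                             stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
    ratio <- function(a) {
      l <- lam(a)
      sqrt(pmax(1 + a * l - l^2, 0)) / (l - a)
    }
    rho <- sd / (mean - lower)
    if (rho >= 0.995)
      stop("target sd too large relative to (mean - lower bound) for a ",
           "lower-truncated normal")
    a <- stats::uniroot(function(a) ratio(a) - rho, c(-40, 20),
                        tol = 1e-12)$root
    l <- lam(a)
    sigma <- sd / sqrt(1 + a * l - l^2)
    mu <- lower - a * sigma
  } else {
    # two-sided: damped fixed-point iteration on the moment maps
    mu <- mean; sigma <- sd
    for (it in seq_len(500)) {
      mo <- tn_moments(mu, sigma, lower, upper)
      dmu <- mean - mo$mean
      rs <- sd / mo$sd
      mu <- mu + 0.8 * dmu
      sigma <- sigma * rs^0.8
      if (abs(dmu) < 1e-9 * sd && abs(rs - 1) < 1e-9) break
    }
  }
  got <- tn_moments(mu, sigma, lower, upper)
  if (abs(got$mean - mean) > 1e-6 * sd || abs(got$sd - sd) > 1e-6 * sd)
    stop("truncated-normal calibration failed to match target moments")
  list(mu = mu, sigma = sigma, lower = lower, upper = upper,
       mean = got$mean, sd = got$sd)
}

# Quantile function of the truncated normal; `p` in (0, 1).
tn_quantile <- function(p, cal) {
  pa <- stats::pnorm(cal$lower, cal$mu, cal$sigma)
  pb <- stats::pnorm(cal$upper, cal$mu, cal$sigma)
  stats::qnorm(pa + p * (pb - pa), cal$mu, cal$sigma)
}

# Draw via a standard-normal latent value (Gaussian copula): w ~ N(0,1)
# induces correlation across quantities while marginals remain the exact
# calibrated truncated normals.
tn_from_latent <- function(w, cal) tn_quantile(stats::pnorm(w), cal)

rtn <- function(n, cal) tn_quantile(stats::runif(n), cal)
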