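# Truncated-normal utilities: moments, moment-matching calibration, and a
# quantile-function sampler. The cohort simulator draws each feature from a
# normal distribution truncated to its physical support (MSA >= 0, UST > 0,
# USR in (0,1)) with parent parameters chosen so the REALIZED post-truncation
# mean/SD match the published cell statistics, which are sample moments.

tnorm_moments <- function(mu, sigma, lower, upper) {
  mu <- unname(mu)
  sigma <- unname(sigma)
  lower <- unname(lower)
  upper <- unname(upper)
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  if (z <= 0) return(c(mean = NA_real_, sd = NA_real_))
  da <- dnorm(a)
  db <- dnorm(b)
  m <- mu + sigma * (da - db) / z
  t_a <- if (is.finite(a)) a * da else 0
  t_b <- if (is.finite(b)) b * db else 0
  v <- sigma^2 * (1 + (t_a - t_b) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for parent (mu, sigma) so that the truncated distribution has the
# target mean/sd. Near the family's dispersion supremum (e.g. a
# zero-truncated normal cannot exceed cv = 1) the best attainable moments are
# returned provided they are within rel_tol of the target.
tnorm_calibrate <- function(mean, sd, lower = -Inf, upper = Inf,
                            rel_tol = 0.02) {
  if (sd == 0) {
    return(list(mu = mean, sigma = 0, realized = c(mean = mean, sd = 0)))
  }
  obj <- function(par) {
    mu <- par[1]
    sigma <- exp(par[2])
    # cap the standardized truncation distance to keep pnorm well-conditioned
    if (is.finite(lower) && (lower - mu) / sigma > 6) return(1e6)
    if (is.finite(lower) && (mu - lower) / sigma > 8 &&
        (!is.finite(upper) || (upper - mu) / sigma > 8)) {
      # effectively untruncated; exact solution exists, keep surface smooth
    }
    mom <- tnorm_moments(mu, sigma, lower, upper)
    if (!all(is.finite(mom))) return(1e6)
    ((mom[1] - mean) / max(abs(mean), 1e-6))^2 +
      ((mom[2] - sd) / sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  mu <- fit$par[1]
  sigma <- exp(fit$par[2])
  realized <- tnorm_moments(mu, sigma, lower, upper)
  rel_err <- max(abs(realized[1] - mean) / max(abs(mean), 1e-6),
                 abs(realized[2] - sd) / sd)
  if (!is.finite(rel_err) || rel_err > rel_tol) {
    abort(sprintf(
      "truncation calibration failed: target mean %.4g / sd %.4g on [%g, %g] unattainable (best rel. error %.2g)",
      mean, sd, lower, upper, rel_err
    ))
  }
  list(mu = mu, sigma = sigma, realized = realized)
}

# Quantile-function sampler. `u` are uniforms; antithetic pairing at the
# call site keeps the realized moments close to the calibrated ones.
qtnorm <- function(u, mu, sigma, lower = -Inf, upper = Inf) {
  if (sigma == 0) return(rep(mu, length(u)))
  pa <- pnorm(lower, mu, sigma)
  pb <- pnorm(upper, mu, sigma)
  qnorm(pa + u * (pb - pa), mu, sigma)
}

# n uniforms in antithetic pairs (u, 1-u); odd n gets one unpaired draw
antithetic_uniforms <- function(n) {
  m <- ceiling(n / 2)
  u <- runif(m)
  head(as.vector(rbind(u, 1 - u)), n)
}

rtnorm_calibrated <- function(n, cal, lower = -Inf, upper = Inf,
                              antithetic = TRUE) {
  if (n == 0) return(numeric(0))
  u <- if (antithetic) antithetic_uniforms(n) else runif(n)
  qtnorm(u, cal$mu, cal$sigma, lower, upper)
}
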