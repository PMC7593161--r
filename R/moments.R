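# Moment-matched sampling distributions for daily incubation behaviour.
#
# The generator draws integer-valued recess counts and off-nest hours by
# rounding (and clamping) latent normal deviates, and continuous daily
# distances from normals truncated below at the geometric minimum a day's
# bouts can realise.  The latent parameters are solved numerically so that
# the *observable* pooled moments (mean/SD of the discretised, truncated,
# coupled draws) hit the requested targets, rather than naively plugging
# the targets into the latent normal.

# pmf of round-then-clamp-to-[0, kmax] of a Normal(mu, sigma) deviate
disc_norm_pmf <- function(mu, sigma, kmax) {
  k <- 0:kmax
  upper <- c(k[-length(k)] + 0.5, Inf)
  lower <- c(-Inf, k[-1] - 0.5)
  pnorm(upper, mu, sigma) - pnorm(lower, mu, sigma)
}

pmf_moments <- function(p, k = seq_along(p) - 1) {
  m <- sum(k * p)
  v <- sum(k^2 * p) - m^2
  c(mean = m, sd = sqrt(max(v, 0)))
}

# latent (mu, sigma) such that the discretised variable has the target moments
fit_disc_norm <- function(mean_target, sd_target, kmax) {
  obj <- function(par) {
    mo <- pmf_moments(disc_norm_pmf(par[1], exp(par[2]), kmax))
    (mo[1] - mean_target)^2 + (mo[2] - sd_target)^2
  }
  fit <- optim(c(mean_target, log(sd_target)), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), kmax = kmax,
       objective = fit$value)
}

# Joint pmf over (recesses r, duration d).  d = 0 when r = 0; given r > 0,
# d is an independent discretised-normal draw clamped to [r, 17 - r]: a day
# needs at least one off-nest hour per bout, and 17 - r is the largest
# off-nest duration that still leaves a one-fix gap between r distinct bouts
# on the 16-slot hourly schedule.  Conditional independence (rather than an
# additive d = r + extra construction) keeps the recess-duration correlation
# at the level the shared zero day and the clamping alone induce.
joint_rd_pmf <- function(p_r, mu_d, sigma_d, slope = 0) {
  rmax <- length(p_r) - 1L
  dmax <- 16L
  pm <- matrix(0, rmax + 1L, dmax + 1L)
  pm[1L, 1L] <- p_r[1L]
  rbar <- sum((0:rmax) * p_r) / max(1 - p_r[1L], 1e-12)
  for (r in seq_len(rmax)) {
    cap <- 17L - r
    z <- disc_norm_pmf(mu_d + slope * (r - rbar), sigma_d, dmax)
    p_d <- numeric(dmax + 1L)
    p_d[r + 1L] <- sum(z[seq_len(r + 1L)])          # round(z) <= r -> r
    if (cap > r) p_d[(r + 2L):(cap + 1L)] <- z[(r + 2L):(cap + 1L)]
    if (cap < dmax)
      p_d[cap + 1L] <- p_d[cap + 1L] + sum(z[(cap + 2L):(dmax + 1L)])
    pm[r + 1L, ] <- p_r[r + 1L] * p_d
  }
  pm
}

# duration latent parameters so the pooled duration moments and the
# recess-duration correlation hit their targets
fit_duration <- function(p_r, mean_target, sd_target, cor_target) {
  rmax <- length(p_r) - 1L
  mo_r <- pmf_moments(p_r)
  rd_cor <- function(pm) {
    mo_d <- pmf_moments(colSums(pm))
    erd <- sum(outer(0:rmax, 0:16) * pm)
    (erd - mo_r[1] * mo_d[1]) / (mo_r[2] * mo_d[2])
  }
  obj <- function(par) {
    pm <- joint_rd_pmf(p_r, par[1], exp(par[2]), par[3])
    mo <- pmf_moments(colSums(pm))
    (mo[1] - mean_target)^2 + (mo[2] - sd_target)^2 +
      (rd_cor(pm) - cor_target)^2
  }
  fit <- optim(c(mean_target, log(sd_target), 0), obj,
               method = "Nelder-Mead",
               control = list(maxit = 10000, reltol = 1e-14))
  pm <- joint_rd_pmf(p_r, fit$par[1], exp(fit$par[2]), fit$par[3])
  list(mu = fit$par[1], sigma = exp(fit$par[2]), slope = fit$par[3],
       achieved_cor = rd_cor(pm), objective = fit$value)
}

# moments of Normal(mu, sigma) truncated below at a
tnorm_lower_moments <- function(mu, sigma, a) {
  alpha <- (a - mu) / sigma
  lz <- pnorm(alpha, lower.tail = FALSE, log.p = TRUE)
  lam <- exp(dnorm(alpha, log = TRUE) - lz)
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + alpha * lam - lam^2)
  c(mean = m, var = max(v, 0))
}

# Distance model: given (r > 0, d), daily distance is min_leg * r (the
# shortest path r bouts can realise while clearing the nest buffer) plus a
# lognormal excursion, exp(Normal(a + b*d, s)).  The shifted lognormal is
# strictly above the geometric bound and right-skewed like observed daily
# distances; (a, b, s) are solved so the pooled mean/SD and the pooled
# distance-duration correlation hit their targets.
fit_distance_model <- function(pm_rd, mean_target, sd_target, cor_target,
                               min_leg) {
  cells <- which(pm_rd > 1e-12, arr.ind = TRUE)
  cells <- cells[cells[, 1] > 1L, , drop = FALSE]  # r > 0
  w <- pm_rd[cells]
  r <- cells[, 1] - 1L
  d <- cells[, 2] - 1L
  mo_d <- pmf_moments(colSums(pm_rd))

  pooled <- function(par) {
    a <- par[1]; b <- par[2]; s <- exp(par[3])
    mu <- a + b * d
    m_c <- min_leg * r + exp(mu + s^2 / 2)
    v_c <- (exp(s^2) - 1) * exp(2 * mu + s^2)
    m1 <- sum(w * m_c)                 # E[dist] (zero cell contributes 0)
    m2 <- sum(w * (v_c + m_c^2))       # E[dist^2]
    exd <- sum(w * m_c * d)            # E[dist * duration]
    sd_dist <- sqrt(max(m2 - m1^2, 1e-12))
    corr <- (exd - m1 * mo_d[1]) / (sd_dist * mo_d[2])
    c(mean = m1, sd = sd_dist, cor = corr)
  }
  obj <- function(par) {
    mo <- pooled(par)
    ((mo[1] - mean_target) / mean_target)^2 +
      ((mo[2] - sd_target) / sd_target)^2 +
      (mo[3] - cor_target)^2
  }
  init <- c(log(mean_target / 2), 0.15, log(0.7))
  fit <- optim(init, obj, method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-13))
  mo <- pooled(fit$par)
  list(a = fit$par[1], b = fit$par[2], s = exp(fit$par[3]),
       min_leg = min_leg, achieved = mo, objective = fit$value)
}

# moments of Normal(mu, sigma) truncated to [a, b]
tnorm_ab_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  dal <- dnorm(al); dbe <- dnorm(be)
  m <- mu + sigma * (dal - dbe) / z
  v <- sigma^2 * (1 + (al * dal - be * dbe) / z - ((dal - dbe) / z)^2)
  c(mean = m, var = max(v, 0))
}

fit_tnorm_ab <- function(mean_target, sd_target, a, b) {
  obj <- function(par) {
    mo <- tnorm_ab_moments(par[1], exp(par[2]), a, b)
    (mo[1] - mean_target)^2 + (sqrt(mo[2]) - sd_target)^2
  }
  fit <- optim(c(mean_target, log(sd_target)), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), a = a, b = b,
       objective = fit$value)
}

# draw from Normal(mu, sigma) truncated below at a, by inverse CDF
rtnorm_lower <- function(n, mu, sigma, a) {
  p_lo <- pnorm(a, mu, sigma)
  u <- p_lo + runif(n) * (1 - p_lo)
  u <- pmin(u, 1 - 1e-16)
  qnorm(u, mu, sigma)
}

rtnorm_ab <- function(n, mu, sigma, a, b) {
  p_lo <- pnorm(a, mu, sigma)
  p_hi <- pnorm(b, mu, sigma)
  qnorm(p_lo + runif(n) * (p_hi - p_lo), mu, sigma)
}
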