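# Shared fixtures, built in code.

# default parameter set, solved once per test file
default_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sim_params()
    cache
  }
})

# one day of fixes from an explicit nest/recess pattern ("N"/"R"), hourly
pattern_day <- function(pattern, nest_xy = c(0, 0), off_dist = 100,
                        day = as.Date("2016-05-01")) {
  n <- length(pattern)
  times <- as.POSIXct(paste(day, sprintf("%02d:00:00", seq(5, length.out = n))),
                      tz = "UTC")
  x <- ifelse(pattern == "R", nest_xy[1] + off_dist, nest_xy[1])
  y <- rep(nest_xy[2], n)
  data.frame(timestamp = times, x = x, y = y)
}

# 2-D Brownian motion track with per-step variance sigma2 * dt
brownian_track <- function(n, sigma2, dt = 60, x0 = 0, y0 = 0) {
  data.frame(timestamp = seq(0, by = dt, length.out = n),
             x = cumsum(c(x0, rnorm(n - 1, 0, sqrt(sigma2 * dt)))),
             y = cumsum(c(y0, rnorm(n - 1, 0, sqrt(sigma2 * dt)))))
}

# independently coded per-row Bernoulli-logit log posterior (test oracle)
naive_log_posterior <- function(params, X, y, prec) {
  total <- 0
  for (i in seq_len(nrow(X))) {
    eta <- sum(X[i, ] * params)
    phi <- 1 / (1 + exp(-eta))
    total <- total + y[i] * log(phi) + (1 - y[i]) * log(1 - phi)
  }
  total + sum(dnorm(params, 0, 1 / sqrt(prec), log = TRUE))
}
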