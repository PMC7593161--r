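# Daily survival models: standardization, log posterior, the compiled
# sampler and convergence diagnostics.

test_that("standardization is exact and location-invariant", {
  set.seed(11)
  d <- data.frame(a = rnorm(200, 5, 3), b = runif(200))
  z <- standardize_covariates(d, c("a", "b"))
  expect_equal(mean(z$a), 0, tolerance = 1e-10)
  expect_equal(sd(z$a), 1, tolerance = 1e-10)
  d2 <- d; d2$a <- d$a + 100
  z2 <- standardize_covariates(d2, c("a", "b"))
  expect_equal(z$a, z2$a, tolerance = 1e-10)
  # a raw change of one SD is one standardized unit
  expect_equal((attr(z, "scale")["a"] + d$a[1] - d$a[1]) /
                 attr(z, "scale")["a"], c(a = 1))
  expect_error(standardize_covariates(data.frame(a = rep(2, 5)), "a"),
               "zero standard deviation")
})

test_that("log_posterior matches an independently coded per-row loop", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(5:20, 1); p <- sample(2:5, 1)
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    y <- rbinom(n, 1, 0.7)
    th <- rnorm(p, 0, 0.8)
    expect_equal(log_posterior(th, X, y, 0.001),
                 naive_log_posterior(th, X, y, 0.001), tolerance = 1e-10)
  }
  # one exposure day at zero parameters: log(1/2) plus the prior terms
  X1 <- matrix(1, 1, 1)
  expect_equal(log_posterior(0, X1, 1, 0.001),
               log(0.5) + dnorm(0, 0, sqrt(1000), log = TRUE))
  # doubling the data doubles the likelihood part exactly
  X <- cbind(1, rnorm(10)); y <- rbinom(10, 1, 0.8); th <- c(0.4, -0.2)
  prior <- sum(dnorm(th, 0, sqrt(1000), log = TRUE))
  ll1 <- log_posterior(th, X, y, 0.001) - prior
  ll2 <- log_posterior(th, rbind(X, X), c(y, y), 0.001) - prior
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
  expect_error(log_posterior(th, X * NA, y), "non-finite")
})

test_that("the sampler is reproducible and tracks the empirical rate", {
  y <- c(rep(1, 250), rep(0, 50))
  X <- matrix(1, 300, 1, dimnames = list(NULL, "(Intercept)"))
  cfg <- mcmc_config("nest", n_iter = 2000, burn_in = 500, thin = 2,
                     seed = 21)
  ch1 <- run_mcmc(X, y, cfg)
  ch2 <- run_mcmc(X, y, cfg)
  expect_identical(ch1$chains, ch2$chains)
  expect_equal(nrow(ch1$chains[[1]]), (2000 - 500) %/% 2)
  draws <- plogis(unlist(lapply(ch1$chains, function(m) m[, 1])))
  expect_lt(abs(median(draws) - 250 / 300), 0.02)
  # burn-in-only adaptation keeps acceptance in a workable range
  expect_true(all(ch1$acceptance > 0.1 & ch1$acceptance < 0.7))
})

test_that("R-hat separates mixed from unmixed chains", {
  set.seed(13)
  a <- matrix(rnorm(1000 * 2), 1000, 2, dimnames = list(NULL, c("p1", "p2")))
  expect_lt(max(gelman_rubin(list(a, a, a))), 1.001)   # identical copies
  plateau <- list(matrix(rnorm(500, 0, 0.1), ncol = 1),
                  matrix(rnorm(500, 10, 0.1), ncol = 1))
  expect_gt(gelman_rubin(plateau)[1], 5)
  mixed <- lapply(1:3, function(i) matrix(rnorm(1000), ncol = 1))
  expect_lt(gelman_rubin(mixed)[1], 1.1)
  expect_error(gelman_rubin(list(a)), "2 chains")
})

test_that("site labels are exchangeable within a year", {
  set.seed(14)
  d <- data.frame(year = rep(c(2015, 2016), each = 30),
                  site = rep(c("A", "B", "A", "B"), each = 15),
                  attempt = sample(1:2, 60, TRUE),
                  concealment_cm = rnorm(60, 90, 20),
                  distance_m = rexp(60, 1 / 300),
                  duration_hr = sample(0:5, 60, TRUE),
                  n_recesses = sample(0:3, 60, TRUE),
                  nage = rep(1:15, 4),
                  nest_alive = rbinom(60, 1, 0.9))
  d$n_recesses <- pmin(d$n_recesses, d$duration_hr)
  spec <- model_spec("nest")
  des1 <- nestrecess:::build_design(d, spec)
  # swap the site labels within 2015 only
  d2 <- d
  d2$site[d2$year == 2015] <- ifelse(d$site[d$year == 2015] == "A", "B", "A")
  des2 <- nestrecess:::build_design(d2, spec)
  th <- rnorm(ncol(des1$X), 0, 0.5)
  names(th) <- des1$param_names
  th2 <- th[des2$param_names]
  th2[c("site:A:2015", "site:B:2015")] <- th[c("site:B:2015", "site:A:2015")]
  expect_equal(log_posterior(th, des1$X, des1$y),
               log_posterior(unname(th2), des2$X, des2$y), tolerance = 1e-10)
})

test_that("fitting recovers a known coefficient on simulated exposure data", {
  p <- sim_params(n_birds = 150, n_sites = 1, years = 2016,
                  beta_nest = c(2.5, 0, 0, 0, -0.4, 0, 0),
                  beta_female = c(10, 0, 0, 0, 0, 0),
                  re_sd_year = 0, re_sd_site = 0,
                  renest_prob = 0, censor_rate = 0, seed = 60)
  ds <- make_dataset(p, emit_tracks = FALSE)
  et <- exposure_from_truth(ds, impute_edges = FALSE)
  spec <- model_spec("nest",
                     covariates = c(conceal = "concealment_cm",
                                    distance = "distance_m",
                                    duration = "duration_hr",
                                    recess = "n_recesses"),
                     random_effects = FALSE)
  fit <- fit_survival(et$covariate, spec,
                      mcmc_config("nest", n_iter = 2500, burn_in = 800,
                                  seed = 3))
  expect_lt(max(fit$rhat), 1.1)
  s <- summarize_draws(posterior_draws(fit, "duration"))
  expect_lt(s$q0.025, -0.4 + 0.35)
  expect_gt(s$q0.975, -0.4 - 0.35)
  expect_gt(s$pd, 0.9)
  # model spec contracts
  expect_error(fit_survival(et$covariate[0, ], spec), "empty")
  expect_false("nage" %in% names(model_spec("female")$covariates))
})
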