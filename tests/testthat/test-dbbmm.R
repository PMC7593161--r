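# Dynamic Brownian bridge: motion variance estimation, UD integration and
# contour areas.

test_that("a linear constant-speed track has vanishing motion variance", {
  tr <- data.frame(timestamp = seq(0, 3600 * 20, by = 3600),
                   x = seq(0, 2000, by = 100), y = 0)
  prof <- estimate_motion_variance(tr, delta = 0)
  expect_lt(max(prof$sigma2), 1e-3)
})

test_that("pure Brownian motion variance is recovered within 25%", {
  set.seed(5)
  s2 <- 4
  tr <- brownian_track(200, s2)
  prof <- estimate_motion_variance(tr, delta = 0)
  expect_lt(abs(median(prof$sigma2) / s2 - 1), 0.25)
})

test_that("a two-regime track yields a profile that tracks the regimes", {
  set.seed(6)
  a <- brownian_track(100, 10)
  b <- brownian_track(100, 1, x0 = a$x[100], y0 = a$y[100])
  tr <- data.frame(timestamp = seq(0, by = 60, length.out = 200),
                   x = c(a$x, b$x), y = c(a$y, b$y))
  for (w in c(7, 11)) {
    prof <- estimate_motion_variance(tr, window = w, delta = 0)
    expect_gt(mean(prof$sigma2[1:100]), 2 * mean(prof$sigma2[101:200]))
  }
  expect_error(estimate_motion_variance(tr[1:2, ], delta = 0), "3 fixes")
})

test_that("a single fix gives an isotropic normal UD with the closed-form contour area", {
  tr <- data.frame(timestamp = 0, x = 0, y = 0)
  ud <- compute_ud(tr, profile = 0, delta = 20, cell_m = 2)
  expect_equal(sum(ud$mass), 1, tolerance = 1e-6)
  for (lev in c(0.5, 0.95, 0.99)) {
    closed <- pi * qchisq(lev, 2) * 20^2 / 1e4
    expect_lt(abs(contour_area(ud, lev) / closed - 1), 0.10)
  }
})

test_that("a two-fix UD matches dense numeric integration of the bridge", {
  tr <- data.frame(timestamp = c(0, 3600), x = c(0, 300), y = c(0, 100))
  s2 <- 5; delta <- 15
  ud <- compute_ud(tr, profile = c(s2, s2), delta = delta, cell_m = 5)
  # oracle: the same closed-form bridge density integrated with 2,000 steps
  dense <- matrix(0, length(ud$x), length(ud$y))
  K <- 2000
  for (k in seq_len(K)) {
    a <- (k - 0.5) / K
    v <- 3600 * a * (1 - a) * s2 + ((1 - a)^2 + a^2) * delta^2
    dense <- dense + outer(dnorm(ud$x, 300 * a, sqrt(v)),
                           dnorm(ud$y, 100 * a, sqrt(v)))
  }
  dense <- dense / sum(dense)
  expect_lt(0.5 * sum(abs(dense - ud$mass)), 1e-3)
})

test_that("every UD is normalized and contour areas behave", {
  set.seed(9)
  for (rep in 1:4) {
    tr <- brownian_track(6, runif(1, 0.5, 8), dt = 3600)
    ud <- compute_ud(tr, profile = rep(runif(1, 0.5, 8), 6), delta = 20,
                     cell_m = 20, n_steps = 12)
    expect_equal(sum(ud$mass), 1, tolerance = 1e-6)
    # monotone in level
    a50 <- contour_area(ud, 0.5); a95 <- contour_area(ud, 0.95)
    a99 <- contour_area(ud, 0.99)
    expect_true(a50 <= a95 && a95 <= a99)
  }
  # all mass in one cell -> one cell's area
  one <- structure(list(x = 5, y = 5, mass = matrix(1, 1, 1), cell_m = 10),
                   class = "ud_grid")
  expect_equal(contour_area(one, 0.99), 100 / 1e4)
  # uniform over N cells at level 0.99 -> ceiling(0.99 N) cells
  N <- 40
  unif <- structure(list(x = seq_len(N), y = 1,
                         mass = matrix(1 / N, N, 1), cell_m = 10),
                    class = "ud_grid")
  expect_equal(contour_area(unif, 0.99), ceiling(0.99 * N) * 100 / 1e4)
})

test_that("smaller location error and motion variance shrink the range", {
  tr <- data.frame(timestamp = c(0, 3600, 7200), x = c(0, 200, 350),
                   y = c(0, 100, 50))
  big <- compute_ud(tr, profile = rep(4, 3), delta = 30, cell_m = 10)
  small <- compute_ud(tr, profile = rep(0.5, 3), delta = 5, cell_m = 10)
  expect_lt(contour_area(small, 0.95), contour_area(big, 0.95))
})

test_that("daily range sizes are produced per calendar day", {
  p <- sim_params(n_birds = 1, seed = 6)
  ds <- make_dataset(p)
  nst <- ds$nests[1, ]
  fx <- ds$fixes[ds$fixes$bird_id == nst$bird_id, ]
  fx <- fx[as.Date(fx$timestamp) >= as.Date(nst$onset) &
           as.Date(fx$timestamp) <= as.Date(nst$termination), ]
  rs <- daily_range_sizes(fx[order(fx$timestamp), ], cell_m = 20,
                          n_steps = 10)
  L <- as.integer(as.Date(nst$termination) - as.Date(nst$onset)) + 1L
  expect_equal(nrow(rs), L)
  expect_true(all(is.finite(rs$area_ha)))
  expect_true(all(rs$area_ha > 0))
})
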