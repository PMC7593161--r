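# Synthetic telemetry generator: day-track construction, fate simulation,
# dataset assembly.

test_that("a no-recess day keeps all 17 fixes inside the nest buffer", {
  set.seed(1)
  trk <- simulate_day_track(c(500, 500), as.Date("2016-04-01"), 0, 0, 0)
  expect_equal(nrow(trk), 17L)
  d <- sqrt((trk$x - 500)^2 + (trk$y - 500)^2)
  expect_true(all(d <= 27.5))
  expect_identical(attr(trk, "distance_m"), 0)
})

test_that("day tracks round-trip through the recess classifier", {
  set.seed(2)
  nest <- c(1000, -200)
  for (case in list(c(2, 3, 400), c(1, 1, 80), c(4, 9, 1200),
                    c(1, 16, 900), c(7, 10, 2000))) {
    trk <- simulate_day_track(nest, as.Date("2016-04-01"),
                              case[1], case[2], case[3])
    m <- daily_metrics(trk, nest)
    expect_identical(m$n_recesses, as.integer(case[1]))
    expect_identical(as.integer(m$duration_hr), as.integer(case[2]))
    expect_equal(m$distance_m, attr(trk, "distance_m"), tolerance = 1e-9)
    b <- extract_bouts(trk, nest)
    expect_equal(nrow(b), case[1])
    expect_equal(sum(b$n_fixes), case[2])
  }
})

test_that("impossible bout/duration combinations are rejected", {
  d <- as.Date("2016-04-01")
  expect_error(simulate_day_track(c(0, 0), d, 3, 2, 100), "impossible")
  expect_error(simulate_day_track(c(0, 0), d, 0, 2, 100), "impossible")
  expect_error(simulate_day_track(c(0, 0), d, 2, 17, 100), "16")
  expect_error(simulate_day_track(c(0, 0), d, 8, 10, 100), "impossible")
})

test_that("daily behaviour draws reproduce the pooled target moments", {
  p <- default_params()
  set.seed(33)
  beh <- nestrecess:::draw_daily_behaviour(p, 12000)
  n <- nrow(beh)
  # 3 standard errors of the target SDs
  expect_lt(abs(mean(beh$n_recesses) - 1.62), 3 * 1.24 / sqrt(n))
  expect_lt(abs(mean(beh$duration_hr) - 2.09), 3 * 1.80 / sqrt(n))
  expect_lt(abs(mean(beh$distance_m) - 357.63), 3 * 396.58 / sqrt(n))
  expect_lt(abs(sd(beh$n_recesses) - 1.24), 0.05)
  expect_lt(abs(sd(beh$duration_hr) - 1.80), 0.07)
  expect_lt(abs(sd(beh$distance_m) - 396.58), 20)
  # structural validity of every draw
  pos <- beh$n_recesses > 0
  expect_true(all(beh$duration_hr[pos] >= beh$n_recesses[pos]))
  expect_true(all((beh$duration_hr == 0) == (beh$n_recesses == 0)))
  expect_true(all(beh$duration_hr + pmax(beh$n_recesses - 1, 0) <= 16))
  expect_true(all(beh$distance_m[pos] > 0))
})

test_that("fate simulation follows the logit-scale daily hazard", {
  set.seed(7)
  z <- matrix(rnorm(30 * 6), 30, 6)
  # saturated intercept: survival certain for the whole cycle
  f <- simulate_fates(z, c(10, 0, 0, 0, 0, 0, 0))
  expect_identical(f, rep(1L, 30))
  # symmetric hazard: empirical daily survival near 0.5
  set.seed(8)
  days <- replicate(4000, {
    f <- simulate_fates(matrix(0, 1, 6), rep(0, 7))
    f[1]
  })
  expect_lt(abs(mean(days) - 0.5), 3 * 0.5 / sqrt(4000))
  # intercept at logit(0.95): empirical daily survival near 0.95
  set.seed(9)
  surv <- integer(0)
  while (length(surv) < 5000) {
    f <- simulate_fates(matrix(0, 30, 6), c(qlogis(0.95), rep(0, 6)))
    surv <- c(surv, f)
  }
  expect_lt(abs(mean(surv) - 0.95), 3 * sqrt(0.95 * 0.05 / length(surv)))
})

test_that("datasets are deterministic given the seed", {
  p <- sim_params(n_birds = 5, seed = 77)
  d1 <- make_dataset(p)
  d2 <- make_dataset(p)
  expect_identical(d1$fixes, d2$fixes)
  expect_identical(d1$nests, d2$nests)
  expect_identical(d1$truth, d2$truth)
})

test_that("dataset structure respects fates, censoring and renesting", {
  # saturate the nest hazard so any <3-day incubation could only come from
  # forced censoring, then switch censoring off
  p <- sim_params(n_birds = 25, censor_rate = 0, seed = 12,
                  beta_nest = c(8, 0, 0, 0, 0, 0, 0))
  ds <- make_dataset(p, emit_tracks = FALSE)
  len <- as.integer(as.Date(ds$nests$termination) -
                    as.Date(ds$nests$onset)) + 1L
  expect_true(all(len >= 3))                      # censor rate 0
  expect_gte(nrow(ds$nests), p$n_birds)           # renesting only adds nests
  # dead female implies a terminated nest the same day
  tr <- ds$truth
  for (nid in unique(tr$nest_id)) {
    rows <- tr[tr$nest_id == nid, ]
    expect_true(all(diff(rows$nest_alive) <= 0))
    expect_true(all(diff(rows$female_alive) <= 0))
    if (any(rows$female_alive == 0))
      expect_equal(rows$nest_alive[nrow(rows)], 0L)
  }
})

test_that("no GPS fixes are emitted after a nest's termination day", {
  p <- sim_params(n_birds = 6, seed = 5)
  ds <- make_dataset(p)
  fx <- ds$fixes
  fx$date <- as.Date(fx$timestamp)
  for (k in seq_len(nrow(ds$nests))) {
    nst <- ds$nests[k, ]
    nxt <- ds$nests[ds$nests$bird_id == nst$bird_id &
                    ds$nests$attempt == nst$attempt + 1, ]
    upper <- if (nrow(nxt)) as.Date(nxt$onset) - 1 else as.Date("2100-01-01")
    span <- fx[fx$bird_id == nst$bird_id &
               fx$date > as.Date(nst$termination) & fx$date <= upper, ]
    expect_equal(nrow(span), 0L)
  }
})
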