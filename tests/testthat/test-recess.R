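# Recess classification, bout extraction, daily metrics, onset detection,
# exposure-table assembly and the collinearity screen.

test_that("the nest buffer boundary is strict: > buffer is recess", {
  nest <- c(0, 0)
  expect_identical(classify_fix(27.5, 0, nest), "nest")
  expect_identical(classify_fix(0, 0, nest), "nest")
  expect_identical(classify_fix(27.51, 0, nest), "recess")
  expect_identical(classify_fix(3, 4, nest, buffer_m = 5), "nest")
  expect_identical(classify_fix(3.01, 4, nest, buffer_m = 5), "recess")
})

test_that("bouts are maximal runs of consecutive off-nest fixes", {
  df <- pattern_day(c("N", "N", "R", "R", "N", "R", "N"))
  b <- extract_bouts(df, c(0, 0))
  expect_equal(nrow(b), 2L)
  expect_equal(b$n_fixes, c(2L, 1L))
  expect_equal(nrow(extract_bouts(pattern_day(rep("N", 17)), c(0, 0))), 0L)
  all_r <- extract_bouts(pattern_day(rep("R", 17)), c(0, 0))
  expect_equal(nrow(all_r), 1L)
  expect_equal(all_r$n_fixes, 17L)
  expect_equal(nrow(extract_bouts(df[0, ], c(0, 0))), 0L)
})

test_that("daily metrics match hand computation", {
  # all fixes on the nest at identical coordinates
  still <- pattern_day(rep("N", 17), off_dist = 0)
  m0 <- daily_metrics(still, c(0, 0))
  expect_equal(unlist(m0), c(distance_m = 0, duration_hr = 0, n_recesses = 0))
  # nest, 100 m east, nest: 200 m path, 1 hr, 1 recess
  m1 <- daily_metrics(pattern_day(c("N", "R", "N")), c(0, 0))
  expect_equal(m1$distance_m, 200)
  expect_equal(m1$duration_hr, 1)
  expect_equal(m1$n_recesses, 1L)
})

test_that("enlarging the buffer never increases duration or recess count", {
  set.seed(21)
  nest <- c(0, 0)
  for (rep in 1:25) {
    r <- sample(0:4, 1); d <- if (r == 0) 0 else r + sample(0:5, 1)
    trk <- simulate_day_track(nest, as.Date("2016-05-05"), r, d,
                              runif(1, 120 * max(r, 1), 900))
    m1 <- daily_metrics(trk, nest, buffer_m = 27.5)
    m2 <- daily_metrics(trk, nest, buffer_m = 60)
    expect_lte(m2$duration_hr, m1$duration_hr)
    expect_lte(m2$n_recesses, m1$n_recesses)
    # conservation: bout fix counts account for every off-nest fix
    b <- extract_bouts(trk, nest)
    expect_equal(sum(b$n_fixes), m1$duration_hr)
  }
})

test_that("onset detection finds the start of sustained sitting", {
  base <- as.POSIXct("2016-04-01 05:00:00", tz = "UTC")
  hours <- 0:79
  # sitting the whole time: onset at the very first fix
  set.seed(3)
  sit <- data.frame(timestamp = base + hours * 3600,
                    x = rnorm(80, 0, 5), y = rnorm(80, 0, 5))
  expect_equal(detect_onset(sit), sit$timestamp[1])
  # continuously ranging: no onset
  rng <- data.frame(timestamp = base + hours * 3600,
                    x = cumsum(rep(200, 80)), y = 0)
  expect_true(is.na(detect_onset(rng)))
  # ranging then sitting: onset within one fix interval of the transition
  trans <- rbind(rng[1:30, ], data.frame(timestamp = base + (30:79) * 3600,
                                         x = rng$x[30] + rnorm(50, 0, 5),
                                         y = rnorm(50, 0, 5)))
  onset <- detect_onset(trans)
  expect_lte(abs(as.numeric(onset) - as.numeric(trans$timestamp[31])), 3600)
  expect_error(detect_onset(sit[1:3, ]), "24")
})

test_that("exposure tables follow the censoring and imputation rules", {
  p <- sim_params(n_birds = 12, seed = 42)
  ds <- make_dataset(p)
  et <- build_exposure_table(ds$nests, ds$fixes)
  len <- as.integer(as.Date(ds$nests$termination) -
                    as.Date(ds$nests$onset)) + 1L
  # period dataset accounting: one row per observed incubation day
  expect_equal(nrow(et$period), sum(len))
  expect_equal(nrow(et$covariate), sum(len[len >= 3]))
  # a hatched full-cycle nest: all alive, edge rows imputed
  full <- ds$nests$nest_id[ds$nests$nest_fate == "hatched" & len == 30]
  if (length(full)) {
    rows <- et$covariate[et$covariate$nest_id == full[1], ]
    expect_equal(nrow(rows), 30L)
    expect_true(all(rows$nest_alive == 1))
    expect_true(all(rows$imputed[c(1, 30)]))
    expect_false(any(rows$imputed[2:29]))
    interior_mean <- mean(rows$duration_hr[2:29])
    expect_equal(rows$duration_hr[1], interior_mean)
    expect_equal(rows$duration_hr[30], interior_mean)
    expect_equal(rows$nage, rows$day)
  }
  # short nests live only in the period dataset, fate-coded at the last row
  short <- ds$nests$nest_id[len < 3]
  if (length(short)) {
    expect_false(any(et$covariate$nest_id %in% short))
    rows <- et$period[et$period$nest_id == short[1], ]
    expect_equal(nrow(rows), len[match(short[1], ds$nests$nest_id)])
    expect_equal(rows$nest_alive[nrow(rows)], 0L)
  }
  # failed nests end 0; depredated females end 0 and end the nest
  for (k in which(ds$nests$nest_fate == "failed")[1:5]) {
    rows <- et$period[et$period$nest_id == ds$nests$nest_id[k], ]
    expect_equal(rows$nest_alive, c(rep(1L, nrow(rows) - 1L), 0L))
    if (ds$nests$female_fate[k] == "depredated")
      expect_equal(rows$female_alive[nrow(rows)], 0L)
    else expect_true(all(rows$female_alive == 1L))
  }
})

test_that("exposure from truth and from fixes agree on interior days", {
  p <- sim_params(n_birds = 8, seed = 31)
  ds <- make_dataset(p)
  via_fix <- build_exposure_table(ds$nests, ds$fixes)$covariate
  via_truth <- exposure_from_truth(ds)$covariate
  key <- function(d) paste(d$nest_id, d$day)
  m <- match(key(via_fix), key(via_truth))
  expect_false(anyNA(m))
  keep <- !via_fix$imputed
  expect_equal(via_fix$distance_m[keep], via_truth$distance_m[m][keep],
               tolerance = 1e-9)
  expect_equal(via_fix$duration_hr[keep], via_truth$duration_hr[m][keep])
  expect_equal(via_fix$n_recesses[keep], via_truth$n_recesses[m][keep])
})

test_that("the collinearity screen drops the later-priority covariate", {
  set.seed(4)
  n <- 1000
  a <- rnorm(n)
  df <- data.frame(a = a, b = a, c = rnorm(n))
  sc <- screen_collinearity(df, c("a", "b", "c"))
  expect_equal(sc$r["a", "b"], 1)
  expect_identical(sc$dropped, "b")
  # independent columns: nothing dropped
  df2 <- data.frame(x = rnorm(n), y = rnorm(n), z = rnorm(n))
  expect_length(screen_collinearity(df2, c("x", "y", "z"))$dropped, 0)
  # distance/range pair generated at r ~ 0.74: range (later priority) dropped
  dist <- rnorm(n)
  range_ <- 0.74 * dist + sqrt(1 - 0.74^2) * rnorm(n)
  df3 <- data.frame(distance_m = dist, range_ha = range_)
  sc3 <- screen_collinearity(df3, c("distance_m", "range_ha"))
  expect_identical(sc3$dropped, "range_ha")
  expect_gt(abs(sc3$flagged$r[1]), 0.7)
  # zero-variance covariate is rejected by name
  expect_error(screen_collinearity(data.frame(u = rnorm(10), v = 1),
                                   c("u", "v")), "v")
})
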