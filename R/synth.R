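# Synthetic incubation telemetry with the statistical structure the survival
# analysis assumes: an hourly GPS fix schedule (05:00-20:00 plus one nightly
# fix at 23:59), daily recess bouts, per-day behaviour covariates with
# moment-matched pooled distributions, and nest/female fates drawn from a
# known logit-scale daily hazard.

FIX_HOURS <- c(5:20)          # hourly diurnal schedule
N_FIXES_PER_DAY <- 17L        # 16 hourly fixes + 23:59 nightly fix

#' Simulation parameters for synthetic incubation telemetry
#'
#' Builds and validates the parameter set used by [make_dataset()]. Defaults
#' reproduce, in expectation, the pooled daily-behaviour moments of the field
#' system the package models: 1.62 unique recesses per day (SD 1.24), 2.09 hr
#' off the nest per day (SD 1.80), 357.63 m traveled per day (SD 396.58) and
#' mean nest concealment of 92.5 cm (SD 47). Because recess counts are
#' integers, off-nest hours are whole fix-hours constrained by the schedule,
#' and distances are bounded below by the geometry of clearing the nest
#' buffer, the latent distribution parameters are solved numerically at
#' construction time so that the *observable* draws match the target moments
#' (see `$fits` in the returned object).
#'
#' @param n_birds number of radio-tagged females to simulate.
#' @param n_sites number of study sites; each site gets its own planar frame.
#' @param years calendar years spanned by the simulated study.
#' @param incubation_days full incubation cycle length in days (hatch occurs
#'   after this many days of survival).
#' @param mean_recesses_per_day,sd_recesses_per_day target pooled moments of
#'   the daily count of unique recesses.
#' @param mean_duration_hr,sd_duration_hr target pooled moments of daily
#'   off-nest duration (hours; one off-nest fix = one hour).
#' @param mean_daily_distance_m,sd_daily_distance_m target pooled moments of
#'   daily distance traveled (m).
#' @param concealment_mean_cm,concealment_sd_cm target moments of nest
#'   concealment (visual obstruction, cm), truncated to \[0, 200\].
#' @param beta_nest,beta_female true logit-scale coefficient vectors for the
#'   daily survival hazards, on standardized covariates, in the order
#'   (intercept, attempt, conceal, distance, duration, recess\[, nage\]).
#'   Defaults are plausible field-scale values: daily nest survival near 0.95
#'   and daily female survival near 0.995 at average covariates, with a
#'   negative duration effect on nests and a positive one on females.
#' @param re_sd_year,re_sd_site SDs of the year and site-within-year random
#'   intercepts used when simulating fates.
#' @param gps_jitter_m radius (m) of the on-nest fix scatter emulating GPS
#'   error; must be smaller than `buffer_m`.
#' @param buffer_m nest buffer radius (m) separating nest from recess fixes.
#' @param duration_distance_cor target pooled Pearson correlation between
#'   daily duration and daily distance.
#' @param recess_duration_cor target pooled Pearson correlation between the
#'   daily recess count and off-nest duration (these are intrinsically
#'   coupled by the shared no-recess days and the one-hour-per-bout floor;
#'   the default stays below the collinearity screen threshold, matching a
#'   study design in which both covariates enter the model).
#' @param renest_prob probability a female whose nest fails (and who survives)
#'   starts another attempt, up to `max_attempts`.
#' @param censor_rate fraction of nest attempts terminated after only 1-2
#'   days of incubation (exercises the short-nest censoring rules downstream).
#' @param max_attempts maximum nest attempts per female.
#' @param max_recesses upper bound on daily unique recesses.
#' @param seed master integer seed; per-bird substreams are derived from it
#'   deterministically.
#'
#' @return an object of class `sim_params`: a list of the arguments plus
#'   `$fits`, the solved latent distribution parameters, and `$std_ref`, the
#'   population standardization moments applied to covariates inside the
#'   simulated hazard.
#' @export
sim_params <- function(n_birds = 40, n_sites = 8, years = 2014:2018,
                       incubation_days = 30,
                       mean_recesses_per_day = 1.62, sd_recesses_per_day = 1.24,
                       mean_duration_hr = 2.09, sd_duration_hr = 1.80,
                       mean_daily_distance_m = 357.63,
                       sd_daily_distance_m = 396.58,
                       concealment_mean_cm = 92.5, concealment_sd_cm = 47,
                       beta_nest = c(intercept = 3.04, attempt = -0.06,
                                     conceal = 0.06, distance = -0.06,
                                     duration = -0.17, recess = 0.03,
                                     nage = 0.03),
                       beta_female = c(intercept = 5.39, attempt = -0.22,
                                       conceal = 0.15, distance = 0.06,
                                       duration = 0.76, recess = -0.55),
                       re_sd_year = 0.2, re_sd_site = 0.2,
                       gps_jitter_m = 10, buffer_m = 27.5,
                       duration_distance_cor = 0.5,
                       recess_duration_cor = 0.6,
                       renest_prob = 0.5, censor_rate = 0.086,
                       max_attempts = 4L, max_recesses = 7L,
                       seed = 1L) {
  stopifnot(n_birds >= 1, n_sites >= 1, length(years) >= 1,
            incubation_days >= 3,
            sd_recesses_per_day >= 0, sd_duration_hr >= 0,
            sd_daily_distance_m >= 0, concealment_sd_cm >= 0,
            re_sd_year >= 0, re_sd_site >= 0,
            gps_jitter_m >= 0, gps_jitter_m < buffer_m,
            length(beta_nest) == 7, length(beta_female) == 6,
            censor_rate >= 0, censor_rate < 1,
            renest_prob >= 0, renest_prob <= 1)

  fit_r <- fit_disc_norm(mean_recesses_per_day, sd_recesses_per_day,
                         kmax = max_recesses)
  p_r <- disc_norm_pmf(fit_r$mu, fit_r$sigma, max_recesses)
  fit_x <- fit_duration(p_r, mean_duration_hr, sd_duration_hr,
                        recess_duration_cor)
  pm_rd <- joint_rd_pmf(p_r, fit_x$mu, fit_x$sigma, fit_x$slope)
  min_leg <- 2 * (buffer_m + 1)
  fit_dist <- fit_distance_model(pm_rd, mean_daily_distance_m,
                                 sd_daily_distance_m, duration_distance_cor,
                                 min_leg)
  fit_conceal <- fit_tnorm_ab(concealment_mean_cm, concealment_sd_cm, 0, 200)

  std_ref <- list(
    attempt = c(mean = 1.36, sd = 0.66),
    conceal = c(mean = concealment_mean_cm, sd = concealment_sd_cm),
    distance = c(mean = mean_daily_distance_m, sd = sd_daily_distance_m),
    duration = c(mean = mean_duration_hr, sd = sd_duration_hr),
    recess = c(mean = mean_recesses_per_day, sd = sd_recesses_per_day),
    nage = c(mean = (incubation_days + 1) / 2,
             sd = sqrt((incubation_days^2 - 1) / 12)))

  structure(list(
    n_birds = as.integer(n_birds), n_sites = as.integer(n_sites),
    years = as.integer(years), incubation_days = as.integer(incubation_days),
    mean_recesses_per_day = mean_recesses_per_day,
    sd_recesses_per_day = sd_recesses_per_day,
    mean_duration_hr = mean_duration_hr, sd_duration_hr = sd_duration_hr,
    mean_daily_distance_m = mean_daily_distance_m,
    sd_daily_distance_m = sd_daily_distance_m,
    concealment_mean_cm = concealment_mean_cm,
    concealment_sd_cm = concealment_sd_cm,
    beta_nest = beta_nest, beta_female = beta_female,
    re_sd_year = re_sd_year, re_sd_site = re_sd_site,
    gps_jitter_m = gps_jitter_m, buffer_m = buffer_m,
    duration_distance_cor = duration_distance_cor,
    recess_duration_cor = recess_duration_cor,
    renest_prob = renest_prob, censor_rate = censor_rate,
    max_attempts = as.integer(max_attempts),
    max_recesses = as.integer(max_recesses),
    seed = as.integer(seed),
    fits = list(recess = fit_r, duration = fit_x, distance = fit_dist,
                conceal = fit_conceal, min_leg = min_leg),
    std_ref = std_ref), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic incubation study parameters\n")
  cat(sprintf("  %d birds, %d sites, years %d-%d, %d-day incubation cycle\n",
              x$n_birds, x$n_sites, min(x$years), max(x$years),
              x$incubation_days))
  cat(sprintf("  daily behaviour targets: %.2f recesses (SD %.2f), %.2f hr (SD %.2f), %.2f m (SD %.2f)\n",
              x$mean_recesses_per_day, x$sd_recesses_per_day,
              x$mean_duration_hr, x$sd_duration_hr,
              x$mean_daily_distance_m, x$sd_daily_distance_m))
  invisible(x)
}

# Draw n days of (recesses, duration, distance) from the moment-matched
# distributions.  Uses the current RNG stream.
draw_daily_behaviour <- function(params, n) {
  f <- params$fits
  r <- pmax(0L, pmin(as.integer(round(rnorm(n, f$recess$mu, f$recess$sigma))),
                     params$max_recesses))
  p_r <- disc_norm_pmf(f$recess$mu, f$recess$sigma, params$max_recesses)
  rbar <- sum((0:params$max_recesses) * p_r) / max(1 - p_r[1L], 1e-12)
  z <- as.integer(round(rnorm(n, f$duration$mu + f$duration$slope * (r - rbar),
                              f$duration$sigma)))
  d <- ifelse(r == 0L, 0L, pmin(pmax(z, r), 17L - r))
  dist <- numeric(n)
  pos <- which(d > 0L)
  if (length(pos)) {
    fd <- f$distance
    dist[pos] <- fd$min_leg * r[pos] +
      exp(rnorm(length(pos), fd$a + fd$b * d[pos], fd$s))
  }
  data.frame(n_recesses = r, duration_hr = as.integer(d), distance_m = dist)
}

#' Simulate one day of GPS fixes for an incubating bird
#'
#' Emits the full daily fix schedule (hourly 05:00-20:00 plus 23:59) around a
#' nest: exactly `duration_hr` fixes are placed farther than `buffer_m` from
#' the nest, arranged in `n_recesses` maximal runs separated by on-nest
#' fixes, and the off-nest excursion path length (the sum of consecutive-fix
#' legs touching at least one off-nest fix) is solved to equal `distance_m`
#' whenever that is geometrically feasible. On-nest fixes are scattered
#' uniformly within `jitter_m` of the nest, and the nightly 23:59 fix is
#' always on the nest.
#'
#' @param nest_xy numeric length-2, nest coordinates (m, planar frame).
#' @param day a `Date`.
#' @param n_recesses number of distinct recess bouts (0 to 7).
#' @param duration_hr number of off-nest fixes; whole hours, at most 16, at
#'   least `n_recesses` when positive.
#' @param distance_m target off-nest path length for the day (m).
#' @param jitter_m on-nest GPS scatter radius (m), must be `< buffer_m`.
#' @param buffer_m nest buffer radius (m).
#' @return a data.frame with columns `timestamp` (POSIXct, UTC-encoded local
#'   time), `x`, `y`, and attributes `n_recesses`, `duration_hr`,
#'   `distance_m` (realized off-nest path length) and `off` (logical flags).
#' @export
simulate_day_track <- function(nest_xy, day, n_recesses, duration_hr,
                               distance_m, jitter_m = 10, buffer_m = 27.5) {
  r <- as.integer(round(n_recesses))
  d <- as.integer(round(duration_hr))
  if (r < 0 || d < 0)
    stop("n_recesses and duration_hr must be non-negative")
  if (r > d)
    stop(sprintf(
      "impossible combination: %d recess bouts cannot be formed from %d off-nest hours (each bout needs at least one off-nest fix)",
      r, d))
  if (d > 0 && r == 0)
    stop("impossible combination: off-nest fixes (duration_hr > 0) require at least one recess bout")
  if (d > 16L)
    stop("duration_hr cannot exceed the 16 hourly fixes of the daily schedule")
  if (r > 0 && d + (r - 1L) > 16L)
    stop(sprintf(
      "impossible combination: %d bouts totalling %d off-nest hours cannot be separated by on-nest fixes within the 16-slot schedule",
      r, d))
  if (jitter_m >= buffer_m)
    stop("jitter_m must be smaller than buffer_m or on-nest fixes would classify as recesses")

  times <- as.POSIXct(paste(format(day), c(sprintf("%02d:00:00", FIX_HOURS),
                                           "23:59:00")), tz = "UTC")
  off <- logical(N_FIXES_PER_DAY)   # slot 17 (23:59) always on-nest

  # on-nest scatter: uniform in a disk of radius jitter_m
  ang <- runif(N_FIXES_PER_DAY, 0, 2 * pi)
  rad <- jitter_m * sqrt(runif(N_FIXES_PER_DAY))
  xy <- cbind(nest_xy[1] + rad * cos(ang), nest_xy[2] + rad * sin(ang))

  if (r > 0) {
    # bout sizes: composition of d into r positive parts
    sizes <- rep(1L, r)
    if (d > r) {
      extra_fix <- tabulate(sample.int(r, d - r, replace = TRUE), r)
      sizes <- sizes + extra_fix
    }
    # place bouts in the 16 hourly slots with >= 1 on-nest gap between bouts
    free <- 16L - d - (r - 1L)
    gaps <- integer(r + 1L)
    if (free > 0L) gaps <- tabulate(sample.int(r + 1L, free, replace = TRUE),
                                    r + 1L)
    cur <- gaps[1L]
    bout_of <- integer(N_FIXES_PER_DAY)
    for (b in seq_len(r)) {
      idx <- (cur + 1L):(cur + sizes[b])
      off[idx] <- TRUE
      bout_of[idx] <- b
      cur <- cur + sizes[b]
      if (b < r) cur <- cur + 1L + gaps[b + 1L]
    }
    # bout geometry: each bout leaves along a fixed bearing with a tent-shaped
    # radius profile; a single scale factor s is solved so the realized
    # off-nest path length matches distance_m
    theta <- runif(r, 0, 2 * pi)
    w <- vector("list", r)
    for (b in seq_len(r)) {
      k <- sizes[b]
      tent <- pmin(seq_len(k), rev(seq_len(k)))
      w[[b]] <- tent / max(tent)
    }
    realize <- function(s) {
      out <- xy
      for (b in seq_len(r)) {
        idx <- which(bout_of == b)
        radius <- buffer_m + 1 + s * w[[b]]
        out[idx, 1] <- nest_xy[1] + radius * cos(theta[b])
        out[idx, 2] <- nest_xy[2] + radius * sin(theta[b])
      }
      out
    }
    path_off <- function(m) {
      legs <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
      sum(legs[off[-N_FIXES_PER_DAY] | off[-1L]])
    }
    t0 <- path_off(realize(0))
    if (is.finite(distance_m) && distance_m > t0) {
      hi <- 100
      while (path_off(realize(hi)) < distance_m && hi < 1e7) hi <- hi * 2
      s_hat <- uniroot(function(s) path_off(realize(s)) - distance_m,
                       lower = 0, upper = hi, tol = 1e-10)$root
    } else {
      s_hat <- 0   # target below the geometric minimum: use tightest bouts
    }
    xy <- realize(s_hat)
    realized <- path_off(xy)
  } else {
    realized <- 0
  }

  out <- data.frame(timestamp = times, x = xy[, 1], y = xy[, 2])
  attr(out, "n_recesses") <- r
  attr(out, "duration_hr") <- d
  attr(out, "distance_m") <- realized
  attr(out, "off") <- off
  out
}

#' Simulate a daily-survival fate sequence
#'
#' Draws daily Bernoulli survival from an inverse-logit linear predictor on
#' standardized covariates; the sequence terminates at the first failure or
#' at the end of the covariate matrix.
#'
#' @param z matrix of standardized covariates, one row per incubation day,
#'   columns in the order of `beta[-1]`.
#' @param beta logit-scale coefficients `(intercept, covariates...)`.
#' @param re_offset scalar (or per-day) random-effect contribution to the
#'   linear predictor.
#' @return integer vector of survival indicators, one per observed day; all
#'   1 except possibly a terminal 0.
#' @export
simulate_fates <- function(z, beta, re_offset = 0) {
  z <- as.matrix(z)
  stopifnot(ncol(z) == length(beta) - 1L)
  eta <- beta[1L] + drop(z %*% beta[-1L]) + re_offset
  p <- plogis(eta)
  u <- runif(nrow(z))
  alive <- as.integer(u < p)
  death <- which(alive == 0L)
  if (length(death)) alive <- alive[seq_len(death[1L])]
  alive
}

std_z <- function(x, ref) (x - ref["mean"]) / ref["sd"]

#' Generate a complete synthetic incubation dataset
#'
#' Simulates a multi-site, multi-year incubation study: each female nests one
#' or more times (renesting after failure with probability
#' `params$renest_prob`); per-day behaviour covariates are drawn from the
#' moment-matched distributions; nest and female fates are drawn from the
#' logit-scale daily hazards in `params`; and (optionally) the full GPS fix
#' schedule is emitted for every observed incubation day. No fixes are
#' generated after a nest's termination day.
#'
#' @param params a [sim_params()] object.
#' @param emit_tracks if `FALSE`, skip GPS fix generation (fast path for
#'   covariate/fate simulations that do not need coordinates).
#' @return a list of class `nestrecess_dataset` with elements `fixes`
#'   (bird_id, timestamp, x, y), `nests` (one row per nest attempt), `truth`
#'   (one row per nest-day with the realized covariates and survival
#'   indicators), and `params`. True random-effect values and coefficient
#'   vectors are attached to `truth` as attributes.
#' @export
make_dataset <- function(params, emit_tracks = TRUE) {
  p <- params
  stopifnot(inherits(p, "sim_params"))
  site_names <- sprintf("S%02d", seq_len(p$n_sites))

  set.seed(p$seed %% 2147483647L)
  bird_ids <- sprintf("B%03d", seq_len(p$n_birds))
  bird_site <- sample(site_names, p$n_birds, replace = TRUE)
  bird_year <- if (length(p$years) == 1L) rep(p$years, p$n_birds) else
    sample(p$years, p$n_birds, replace = TRUE)

  yr_key <- as.character(p$years)
  sy_key <- as.vector(outer(site_names, p$years, paste, sep = ":"))
  re <- list(
    year_nest = setNames(rnorm(length(yr_key), 0, p$re_sd_year), yr_key),
    year_female = setNames(rnorm(length(yr_key), 0, p$re_sd_year), yr_key),
    site_nest = setNames(rnorm(length(sy_key), 0, p$re_sd_site), sy_key),
    site_female = setNames(rnorm(length(sy_key), 0, p$re_sd_site), sy_key))

  sr <- p$std_ref
  fixes_l <- list(); nests_l <- list(); truth_l <- list()

  for (i in seq_len(p$n_birds)) {
    set.seed((p$seed * 48271 + i * 1009) %% 2147483647L)
    bird <- bird_ids[i]; site <- bird_site[i]; year <- bird_year[i]
    site_offset <- (match(site, site_names) - 1) * 1e5
    season_start <- as.Date(sprintf("%d-03-18", year))
    season_end <- as.Date(sprintf("%d-07-20", year))
    onset <- season_start +
      sample.int(as.integer(season_end - season_start) - p$incubation_days + 1L,
                 1L) - 1L
    re_n <- re$year_nest[as.character(year)] +
      re$site_nest[paste(site, year, sep = ":")]
    re_f <- re$year_female[as.character(year)] +
      re$site_female[paste(site, year, sep = ":")]

    for (attempt in seq_len(p$max_attempts)) {
      nest_id <- sprintf("%s_N%d", bird, attempt)
      nest_xy <- c(site_offset + runif(1, 0, 5000), runif(1, 0, 5000))
      conceal <- rtnorm_ab(1, p$fits$conceal$mu, p$fits$conceal$sigma, 0, 200)

      censored <- runif(1) < p$censor_rate
      if (censored) {
        L <- sample(1:2, 1L)
        beh <- draw_daily_behaviour(p, L)
        nest_alive <- c(rep(1L, L - 1L), 0L)
        female_alive <- rep(1L, L)
        nest_fate <- "failed"; female_fate <- "alive"
      } else {
        beh <- draw_daily_behaviour(p, p$incubation_days)
        z <- cbind(attempt = std_z(attempt, sr$attempt),
                   conceal = std_z(conceal, sr$conceal),
                   distance = std_z(beh$distance_m, sr$distance),
                   duration = std_z(beh$duration_hr, sr$duration),
                   recess = std_z(beh$n_recesses, sr$recess),
                   nage = std_z(seq_len(p$incubation_days), sr$nage))
        fem <- simulate_fates(z[, 1:5, drop = FALSE], p$beta_female, re_f)
        nst <- simulate_fates(z, p$beta_nest, re_n)
        # a dead female terminates her nest the same day (killed at the nest)
        if (length(fem) <= length(nst) && fem[length(fem)] == 0L) {
          L <- length(fem)
          female_fate <- "depredated"; nest_fate <- "failed"
          female_alive <- fem
          nest_alive <- c(rep(1L, L - 1L), 0L)
        } else {
          L <- length(nst)
          female_alive <- rep(1L, L)
          female_fate <- "alive"
          if (nst[L] == 0L) {
            nest_fate <- "failed"; nest_alive <- nst
          } else {
            nest_fate <- "hatched"; nest_alive <- nst
          }
        }
        beh <- beh[seq_len(L), , drop = FALSE]
      }

      termination <- onset + L - 1L
      dates <- onset + seq_len(L) - 1L

      if (emit_tracks) {
        for (j in seq_len(L)) {
          trk <- simulate_day_track(nest_xy, dates[j], beh$n_recesses[j],
                                    beh$duration_hr[j], beh$distance_m[j],
                                    p$gps_jitter_m, p$buffer_m)
          beh$distance_m[j] <- attr(trk, "distance_m")
          fixes_l[[length(fixes_l) + 1L]] <-
            data.frame(bird_id = bird, timestamp = trk$timestamp,
                       x = trk$x, y = trk$y)
        }
      }

      nests_l[[length(nests_l) + 1L]] <- data.frame(
        nest_id = nest_id, bird_id = bird, site = site, year = year,
        attempt = attempt, onset = onset, termination = termination,
        nest_fate = nest_fate, female_fate = female_fate,
        nest_x = nest_xy[1], nest_y = nest_xy[2], concealment_cm = conceal)
      truth_l[[length(truth_l) + 1L]] <- data.frame(
        nest_id = nest_id, bird_id = bird, site = site, year = year,
        attempt = attempt, concealment_cm = conceal,
        date = dates, day = seq_len(L),
        n_recesses = beh$n_recesses, duration_hr = beh$duration_hr,
        distance_m = beh$distance_m,
        nest_alive = nest_alive, female_alive = female_alive)

      if (nest_fate == "hatched" || female_fate == "depredated") break
      if (attempt == p$max_attempts || runif(1) >= p$renest_prob) break
      onset <- termination + sample(7:15, 1L)
      if (onset + p$incubation_days - 1L > season_end) break
    }
  }

  fixes <- if (length(fixes_l)) do.call(rbind, fixes_l) else
    data.frame(bird_id = character(), timestamp = as.POSIXct(character()),
               x = numeric(), y = numeric())
  nests <- do.call(rbind, nests_l)
  truth <- do.call(rbind, truth_l)
  rownames(nests) <- rownames(truth) <- NULL
  attr(truth, "beta_nest") <- p$beta_nest
  attr(truth, "beta_female") <- p$beta_female
  attr(truth, "random_effects") <- re
  structure(list(fixes = fixes, nests = nests, truth = truth, params = p),
            class = "nestrecess_dataset")
}

#' @export
print.nestrecess_dataset <- function(x, ...) {
  cat(sprintf("Synthetic incubation dataset: %d nests, %d birds, %d fixes, %d nest-days\n",
              nrow(x$nests), length(unique(x$nests$bird_id)),
              nrow(x$fixes), nrow(x$truth)))
  invisible(x)
}

#' Exposure tables straight from simulation truth
#'
#' Builds the covariate and period exposure-day tables from a dataset's truth
#' records (bypassing GPS classification), applying the same first/last-day
#' mean imputation and short-nest censoring as [build_exposure_table()].
#' Useful for parameter-recovery experiments that do not need coordinates.
#'
#' @param dataset a [make_dataset()] result.
#' @param min_days nests incubated fewer than this many days are excluded
#'   from the covariate table (kept in the period table).
#' @param impute_edges replace first/last-day behaviour covariates by the
#'   nest's interior means, as the field protocol does (those days' metrics
#'   are poorly estimated). Set `FALSE` to keep the generator's true values
#'   on every day, e.g. for sampler parameter-recovery experiments where
#'   edge imputation would attenuate the very signal under study.
#' @return list with `covariate` and `period` exposure data.frames.
#' @export
exposure_from_truth <- function(dataset, min_days = 3, impute_edges = TRUE) {
  tr <- dataset$truth
  day_table <- data.frame(
    nest_id = tr$nest_id, bird_id = tr$bird_id, site = tr$site,
    year = tr$year, attempt = tr$attempt,
    concealment_cm = tr$concealment_cm, date = tr$date, day = tr$day,
    distance_m = tr$distance_m, duration_hr = as.numeric(tr$duration_hr),
    n_recesses = as.numeric(tr$n_recesses),
    nest_alive = tr$nest_alive, female_alive = tr$female_alive,
    flagged = FALSE)
  assemble_exposure(day_table, min_days = min_days,
                    impute_edges = impute_edges)
}
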