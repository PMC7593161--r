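# Dynamic Brownian bridge movement model: per-fix motion variance by
# sliding-window leave-one-out likelihood with change-point selection, a
# numerically integrated utilization distribution (UD) on a regular grid,
# and highest-density contour areas ("daily range size").
#
# Time is handled in seconds; the Brownian motion variance sigma2_m is in
# m^2/s.  Along a segment between fixes a (time 0) and b (time T), the
# bridge position at fractional time alpha is Normal with mean
# a + alpha*(b - a) and per-coordinate variance
#   T * alpha * (1 - alpha) * sigma2_m + (1 - alpha)^2 * delta^2 + alpha^2 * delta^2
# where delta is the telemetry location error.

bridge_loglik <- function(x, y, t, idx, sigma2, delta) {
  len <- length(idx)
  pts <- if (len >= 3L) seq(2L, len - 1L, by = 2L) else integer()
  if (!length(pts)) return(NA_real_)
  ll <- 0
  for (k in pts) {
    i0 <- idx[k - 1L]; i1 <- idx[k]; i2 <- idx[k + 1L]
    tt <- t[i2] - t[i0]
    if (tt <= 0) next
    a <- (t[i1] - t[i0]) / tt
    v <- tt * a * (1 - a) * sigma2 + ((1 - a)^2 + a^2) * delta^2
    if (v <= 0) return(-Inf)
    mx <- x[i0] + a * (x[i2] - x[i0])
    my <- y[i0] + a * (y[i2] - y[i0])
    ll <- ll + dnorm(x[i1], mx, sqrt(v), log = TRUE) +
      dnorm(y[i1], my, sqrt(v), log = TRUE)
  }
  ll
}

n_bridge_points <- function(len) if (len >= 3L) length(seq(2L, len - 1L, by = 2L)) else 0L

mle_sigma2 <- function(x, y, t, idx, delta,
                       lower = 1e-4, upper = 1e8) {
  opt <- optimize(function(ls) -bridge_loglik(x, y, t, idx, exp(ls), delta),
                  interval = c(log(lower), log(upper)), tol = 1e-6)
  list(sigma2 = exp(opt$minimum), ll = -opt$objective)
}

#' Estimate the dynamic Brownian motion variance profile
#'
#' Slides a window of `window` fixes along the track; within each window the
#' motion variance maximizes the leave-one-out bridge likelihood of the
#' odd interior fixes, and a single change point (leaving at least `margin`
#' fixes on each side) is accepted when it lowers the BIC relative to the
#' constant-variance window. Each fix's variance is the mean over all
#' windows covering it. Tracks shorter than the window fall back to a single
#' global estimate.
#'
#' @param track data.frame with `timestamp` (POSIXct or numeric seconds),
#'   `x`, `y`, time-ordered.
#' @param window odd window size in fixes.
#' @param margin odd margin (minimum fixes on each side of a change point).
#' @param delta telemetry location error SD (m).
#' @return object of class `motion_variance_profile`: list with per-fix
#'   `sigma2` (m^2/s), and the settings.
#' @export
estimate_motion_variance <- function(track, window = 7, margin = 3,
                                     delta = 20) {
  n <- nrow(track)
  if (n < 3L) stop("motion variance is not estimable from fewer than 3 fixes")
  stopifnot(window > 2 * margin, margin >= 1)
  x <- track$x; y <- track$y; t <- as.numeric(track$timestamp)
  if (n < window) {
    est <- mle_sigma2(x, y, t, seq_len(n), delta)
    prof <- rep(est$sigma2, n)
  } else {
    acc <- numeric(n); cnt <- numeric(n)
    for (i in seq_len(n - window + 1L)) {
      idx <- i:(i + window - 1L)
      single <- mle_sigma2(x, y, t, idx, delta)
      m <- n_bridge_points(window)
      best_bic <- -2 * single$ll + log(m)
      best_assign <- rep(single$sigma2, window)
      for (cp in margin:(window - margin)) {
        li <- idx[1:cp]; ri <- idx[(cp + 1L):window]
        ml <- n_bridge_points(length(li)); mr <- n_bridge_points(length(ri))
        # a side with a single likelihood point saturates its variance MLE
        # (the information criterion is undefined at n <= k); require two
        if (ml < 2L || mr < 2L) next
        le <- mle_sigma2(x, y, t, li, delta)
        re <- mle_sigma2(x, y, t, ri, delta)
        bic <- -2 * (le$ll + re$ll) + 2 * log(m)
        if (bic < best_bic) {
          best_bic <- bic
          best_assign <- c(rep(le$sigma2, cp), rep(re$sigma2, window - cp))
        }
      }
      acc[idx] <- acc[idx] + best_assign
      cnt[idx] <- cnt[idx] + 1
    }
    prof <- acc / cnt
  }
  structure(list(sigma2 = prof, window = window, margin = margin,
                 delta = delta), class = "motion_variance_profile")
}

#' Compute a Brownian bridge utilization distribution on a grid
#'
#' Numerically integrates the bridge normal densities along every segment of
#' the track (midpoint rule, `n_steps` steps per fix interval, each step
#' weighted by the segment duration) on a regular grid of `cell_m` cells
#' covering the fixes padded by `pad_sd` maximum bridge SDs, then normalizes
#' the cell masses to 1. A single fix yields an isotropic normal of SD
#' `delta`.
#'
#' @param track data.frame with `timestamp`, `x`, `y`.
#' @param profile a [estimate_motion_variance()] result, or a numeric vector
#'   of per-fix motion variances.
#' @param delta location error SD (m); taken from `profile` when available.
#' @param cell_m grid cell size (m).
#' @param n_steps integration steps per fix interval (>= 10 recommended).
#' @param pad_sd grid padding in units of the largest bridge SD; the default
#'   3.5 keeps enough far-field mass on the grid for accurate 99% isopleths.
#' @return object of class `ud_grid`: list with cell-center coordinates `x`,
#'   `y`, the `mass` matrix (rows follow `x`), and `cell_m`.
#' @export
compute_ud <- function(track, profile, delta = NULL, cell_m = 10,
                       n_steps = 50, pad_sd = 3.5) {
  if (inherits(profile, "motion_variance_profile")) {
    sigma2 <- profile$sigma2
    if (is.null(delta)) delta <- profile$delta
  } else sigma2 <- as.numeric(profile)
  if (is.null(delta)) stop("delta must be supplied")
  n <- nrow(track)
  stopifnot(length(sigma2) == n, n >= 1)
  x <- track$x; y <- track$y; t <- as.numeric(track$timestamp)

  if (n == 1L) {
    if (delta <= 0) stop("a single-fix UD needs a positive location error")
    max_sd <- delta
  } else {
    dt <- diff(t)
    s2seg <- (sigma2[-n] + sigma2[-1L]) / 2
    max_sd <- max(delta, sqrt(pmax(dt, 0) * 0.25 * s2seg + 0.5 * delta^2))
  }
  pad <- pad_sd * max_sd
  xs <- grid_centers(range(x), pad, cell_m)
  ys <- grid_centers(range(y), pad, cell_m)
  mass <- matrix(0, length(xs), length(ys))

  if (n == 1L) {
    mass <- outer(dnorm(xs, x, delta), dnorm(ys, y, delta))
  } else {
    for (i in seq_len(n - 1L)) {
      T_i <- t[i + 1L] - t[i]
      if (T_i <= 0) {
        warning("zero-duration segment at fix ", i, " skipped")
        next
      }
      s2 <- s2seg[i]
      for (k in seq_len(n_steps)) {
        a <- (k - 0.5) / n_steps
        v <- T_i * a * (1 - a) * s2 + ((1 - a)^2 + a^2) * delta^2
        mx <- x[i] + a * (x[i + 1L] - x[i])
        my <- y[i] + a * (y[i + 1L] - y[i])
        mass <- mass + (T_i / n_steps) *
          outer(dnorm(xs, mx, sqrt(v)), dnorm(ys, my, sqrt(v)))
      }
    }
  }
  tot <- sum(mass)
  if (tot <= 0) stop("UD has zero mass on the grid; enlarge the grid")
  structure(list(x = xs, y = ys, mass = mass / tot, cell_m = cell_m),
            class = "ud_grid")
}

grid_centers <- function(rng, pad, cell_m) {
  lo <- rng[1] - pad; hi <- rng[2] + pad
  k <- max(1L, ceiling((hi - lo) / cell_m))
  lo + (seq_len(k) - 0.5) * cell_m   # centers of k cells of side cell_m
}

#' Highest-density contour area of a utilization distribution
#'
#' Area of the smallest set of highest-mass cells whose cumulative mass
#' reaches `level`.
#'
#' @param ud a [compute_ud()] result.
#' @param level contour level in (0, 1); 0.99 gives the 99% daily range.
#' @return area in hectares.
#' @export
contour_area <- function(ud, level = 0.99) {
  stopifnot(level > 0, level < 1)
  p <- sort(as.numeric(ud$mass), decreasing = TRUE)
  ncell <- which(cumsum(p) >= level - 1e-12)[1L]
  ncell * ud$cell_m^2 / 1e4
}

#' Daily range sizes for one incubation track
#'
#' Estimates the motion variance profile over the whole track (a sliding
#' window cannot live inside a single day's fixes), then integrates a UD for
#' each calendar day from that day's fixes and the matching slice of the
#' profile, and returns the contour area.
#'
#' @param track data.frame `timestamp`, `x`, `y` for one bird's incubation
#'   window, time-ordered.
#' @param window,margin,delta see [estimate_motion_variance()].
#' @param cell_m,n_steps,pad_sd see [compute_ud()].
#' @param level contour level.
#' @return data.frame with `date` and `area_ha` (NA for days with < 2 fixes).
#' @export
daily_range_sizes <- function(track, window = 7, margin = 3, delta = 20,
                              cell_m = 10, n_steps = 15, pad_sd = 3.5,
                              level = 0.99) {
  prof <- estimate_motion_variance(track, window, margin, delta)
  dates <- as.Date(track$timestamp)
  out <- lapply(unique(dates), function(dd) {
    sel <- dates == dd
    if (sum(sel) < 2L) return(data.frame(date = dd, area_ha = NA_real_))
    ud <- compute_ud(track[sel, , drop = FALSE], prof$sigma2[sel],
                     delta = delta, cell_m = cell_m, n_steps = n_steps,
                     pad_sd = pad_sd)
    data.frame(date = dd, area_ha = contour_area(ud, level))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Daily range sizes for every nest in a dataset
#'
#' @param nests nest table; @param fixes fix table (schemas as in
#'   [build_exposure_table()]).
#' @param ... passed to [daily_range_sizes()].
#' @return data.frame `nest_id`, `date`, `area_ha`.
#' @export
range_sizes_for_nests <- function(nests, fixes, ...) {
  fixes$date <- as.Date(fixes$timestamp)
  out <- list()
  for (k in seq_len(nrow(nests))) {
    nst <- nests[k, ]
    bf <- fixes[fixes$bird_id == nst$bird_id &
                fixes$date >= as.Date(nst$onset) &
                fixes$date <= as.Date(nst$termination), , drop = FALSE]
    if (nrow(bf) < 3L) next
    bf <- bf[order(bf$timestamp), , drop = FALSE]
    rs <- daily_range_sizes(bf, ...)
    rs$nest_id <- nst$nest_id
    out[[length(out) + 1L]] <- rs[, c("nest_id", "date", "area_ha")]
  }
  if (!length(out)) return(data.frame(nest_id = character(),
                                      date = as.Date(character()),
                                      area_ha = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
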