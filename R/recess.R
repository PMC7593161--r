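# Recess classification and daily movement metrics.
#
# A fix is a recess location iff it lies strictly farther than the nest
# buffer (default 27.5 m) from the nest; fixes at or inside the buffer are
# incubation (nest) locations.  A unique recess is a maximal run of
# consecutive recess fixes within one calendar day.

#' Classify GPS fixes as nest or recess locations
#'
#' @param x,y fix coordinates (m), vectorized.
#' @param nest_xy numeric length-2 nest coordinates.
#' @param buffer_m nest buffer radius (m); a fix is a recess location iff its
#'   Euclidean distance from the nest is strictly greater than `buffer_m`.
#' @return character vector, `"recess"` or `"nest"`.
#' @export
classify_fix <- function(x, y, nest_xy, buffer_m = 27.5) {
  stopifnot(all(is.finite(x)), all(is.finite(y)), all(is.finite(nest_xy)))
  d <- sqrt((x - nest_xy[1])^2 + (y - nest_xy[2])^2)
  ifelse(d > buffer_m, "recess", "nest")
}

is_off_nest <- function(x, y, nest_xy, buffer_m) {
  sqrt((x - nest_xy[1])^2 + (y - nest_xy[2])^2) > buffer_m
}

#' Extract recess bouts from one day of fixes
#'
#' Bouts are maximal runs of consecutive off-nest fixes within the supplied
#' (time-ordered, single-day) fix table.
#'
#' @param day_fixes data.frame with `timestamp`, `x`, `y`, sorted by time.
#' @param nest_xy nest coordinates.
#' @param buffer_m nest buffer radius (m).
#' @return data.frame with one row per bout: `start`, `end` (timestamps),
#'   `n_fixes`, `max_displacement_m` (farthest fix from the nest) and
#'   `path_m` (summed consecutive-fix legs within the bout).
#' @export
extract_bouts <- function(day_fixes, nest_xy, buffer_m = 27.5) {
  empty <- data.frame(start = as.POSIXct(character()),
                      end = as.POSIXct(character()),
                      n_fixes = integer(), max_displacement_m = numeric(),
                      path_m = numeric())
  if (is.null(day_fixes) || nrow(day_fixes) == 0L) return(empty)
  off <- is_off_nest(day_fixes$x, day_fixes$y, nest_xy, buffer_m)
  if (!any(off)) return(empty)
  runs <- rle(off)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    dx <- day_fixes$x[idx]; dy <- day_fixes$y[idx]
    path <- if (length(idx) > 1L) sum(sqrt(diff(dx)^2 + diff(dy)^2)) else 0
    data.frame(start = day_fixes$timestamp[idx[1L]],
               end = day_fixes$timestamp[idx[length(idx)]],
               n_fixes = length(idx),
               max_displacement_m = max(sqrt((dx - nest_xy[1])^2 +
                                             (dy - nest_xy[2])^2)),
               path_m = path)
  })
  do.call(rbind, out)
}

#' Daily movement metrics from one day of fixes
#'
#' Computes the three daily behaviour covariates: recess duration (one hour
#' per off-nest fix, the nightly 23:59 fix weighted by `night_fix_weight`),
#' number of unique recesses (maximal off-nest runs), and daily distance
#' traveled. By default distance sums only the legs between consecutive
#' fixes where at least one endpoint is off the nest, so that a day spent
#' entirely on the nest has distance ~0 regardless of GPS scatter; set
#' `include_nest_legs = TRUE` to sum every consecutive-fix leg.
#'
#' @inheritParams extract_bouts
#' @param include_nest_legs include legs between two consecutive on-nest
#'   fixes in the daily distance.
#' @param night_fix_weight duration contribution (hours) of an off-nest
#'   nightly fix.
#' @return list with `distance_m`, `duration_hr`, `n_recesses`.
#' @export
daily_metrics <- function(day_fixes, nest_xy, buffer_m = 27.5,
                          include_nest_legs = FALSE, night_fix_weight = 1) {
  if (is.null(day_fixes) || nrow(day_fixes) == 0L)
    return(list(distance_m = NA_real_, duration_hr = NA_real_,
                n_recesses = NA_real_))
  off <- is_off_nest(day_fixes$x, day_fixes$y, nest_xy, buffer_m)
  hrs <- as.integer(format(day_fixes$timestamp, "%H"))
  wt <- ifelse(hrs >= 21L, night_fix_weight, 1)
  duration <- sum(wt[off])
  runs <- rle(off)
  n_rec <- sum(runs$values)
  n <- nrow(day_fixes)
  if (n > 1L) {
    legs <- sqrt(diff(day_fixes$x)^2 + diff(day_fixes$y)^2)
    use <- if (include_nest_legs) rep(TRUE, n - 1L) else off[-n] | off[-1L]
    distance <- sum(legs[use])
  } else distance <- 0
  list(distance_m = distance, duration_hr = duration, n_recesses = n_rec)
}

#' Detect onset of incubation from a fix stream
#'
#' Returns the earliest fix time `t` such that every fix in `[t, t + 24 hr]`
#' lies within `buffer_m` of the centroid of those fixes (locations "fixed
#' around a central point" for a day), or `NA` if no such window exists.
#'
#' @param fixes data.frame with `timestamp`, `x`, `y` for one bird, sorted.
#' @param buffer_m clustering radius (m); the nest buffer radius is used by
#'   default.
#' @param window_hr window length in hours.
#' @return POSIXct onset time, or `NA`.
#' @export
detect_onset <- function(fixes, buffer_m = 27.5, window_hr = 24) {
  n <- nrow(fixes)
  t <- as.numeric(fixes$timestamp)
  if (n < 2L || (t[n] - t[1L]) < window_hr * 3600)
    stop("need at least ", window_hr, " hr of fixes to detect onset")
  for (i in seq_len(n)) {
    if (t[n] - t[i] < window_hr * 3600) break
    j <- max(which(t <= t[i] + window_hr * 3600))
    xs <- fixes$x[i:j]; ys <- fixes$y[i:j]
    cx <- mean(xs); cy <- mean(ys)
    if (all(sqrt((xs - cx)^2 + (ys - cy)^2) <= buffer_m))
      return(fixes$timestamp[i])
  }
  as.POSIXct(NA)
}

# Shared assembler for exposure-day tables.  `day_table` has one row per
# nest-day with raw metrics, fate indicators and a `flagged` column marking
# days whose metrics are unreliable.  First and last incubation days (and
# flagged days) get the nest's across-day interior means for the behavioural
# covariates; nests with fewer than `min_days` observed days are excluded
# from the covariate table but kept in the period table.
assemble_exposure <- function(day_table, min_days = 3, impute_edges = TRUE) {
  beh_cols <- intersect(c("distance_m", "duration_hr", "n_recesses",
                          "range_ha"), names(day_table))
  pieces <- split(day_table, day_table$nest_id)
  out <- lapply(pieces, function(dt) {
    dt <- dt[order(dt$day), , drop = FALSE]
    L <- nrow(dt)
    edge <- if (impute_edges) dt$day == 1L | dt$day == L else rep(FALSE, L)
    impute <- edge | dt$flagged
    interior <- !impute
    for (cc in beh_cols) {
      if (any(interior)) {
        dt[[cc]][impute] <- mean(dt[[cc]][interior], na.rm = TRUE)
      } else {
        dt[[cc]] <- NA_real_
      }
    }
    dt$imputed <- impute
    dt$n_days <- L
    dt
  })
  period <- do.call(rbind, out)
  rownames(period) <- NULL
  period$nage <- period$day
  covariate <- period[period$n_days >= min_days, , drop = FALSE]
  rownames(covariate) <- NULL
  list(covariate = covariate, period = period)
}

#' Build exposure-day tables from nest records and GPS fixes
#'
#' For every nest, computes the daily behaviour metrics over the incubation
#' window (onset to termination), applies the exposure-period rules -- the
#' first and last incubation days contribute exposure rows but carry the
#' nest's across-day mean covariates, days with under half the scheduled
#' fixes are likewise mean-imputed, and nests incubated fewer than
#' `min_days` days are excluded from the covariate table while remaining in
#' the intercept-only (period survival) table -- and codes daily fates: all
#' rows 1 except a terminal 0 for a failed nest (or a depredated female).
#'
#' @param nests nest table (`nest_id`, `bird_id`, `site`, `year`, `attempt`,
#'   `onset`, `termination`, `nest_fate`, `female_fate`, `nest_x`, `nest_y`,
#'   `concealment_cm`).
#' @param fixes fix table (`bird_id`, `timestamp`, `x`, `y`).
#' @param range_sizes optional data.frame (`nest_id`, `date`, `area_ha`) of
#'   daily range sizes to join as a covariate.
#' @param buffer_m nest buffer radius (m).
#' @param min_days short-nest censoring threshold (days).
#' @param min_coverage flag a day whose fix count is below this fraction of
#'   the 17-fix schedule and mean-impute its covariates.
#' @param include_nest_legs,night_fix_weight passed to [daily_metrics()].
#' @return list with `covariate` and `period` exposure data.frames (columns
#'   `nest_id`, ids, `day`, `nage`, `date`, fates `nest_alive`/`female_alive`,
#'   behaviour covariates, `imputed`, `n_days`).
#' @export
build_exposure_table <- function(nests, fixes, range_sizes = NULL,
                                 buffer_m = 27.5, min_days = 3,
                                 min_coverage = 0.5,
                                 include_nest_legs = FALSE,
                                 night_fix_weight = 1) {
  fixes$date <- as.Date(fixes$timestamp)
  rows <- list()
  for (k in seq_len(nrow(nests))) {
    nst <- nests[k, ]
    onset <- as.Date(nst$onset); term <- as.Date(nst$termination)
    L <- as.integer(term - onset) + 1L
    bf <- fixes[fixes$bird_id == nst$bird_id &
                fixes$date >= onset & fixes$date <= term, , drop = FALSE]
    if (nrow(bf) == 0L) {
      warning("nest ", nst$nest_id, " has no GPS fixes in its incubation window; excluded")
      next
    }
    nest_xy <- c(nst$nest_x, nst$nest_y)
    dates <- onset + seq_len(L) - 1L
    mets <- lapply(dates, function(dd) {
      df <- bf[bf$date == dd, , drop = FALSE]
      df <- df[order(df$timestamp), , drop = FALSE]
      m <- daily_metrics(df, nest_xy, buffer_m,
                         include_nest_legs = include_nest_legs,
                         night_fix_weight = night_fix_weight)
      c(distance_m = m$distance_m, duration_hr = m$duration_hr,
        n_recesses = m$n_recesses, n_fix = nrow(df))
    })
    mets <- do.call(rbind, mets)
    flagged <- mets[, "n_fix"] < min_coverage * 17 | !is.finite(mets[, "distance_m"])
    nest_alive <- rep(1L, L)
    female_alive <- rep(1L, L)
    if (identical(nst$nest_fate, "failed")) nest_alive[L] <- 0L
    if (identical(nst$female_fate, "depredated")) {
      female_alive[L] <- 0L
      nest_alive[L] <- 0L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      nest_id = nst$nest_id, bird_id = nst$bird_id, site = nst$site,
      year = nst$year, attempt = nst$attempt,
      concealment_cm = nst$concealment_cm,
      date = dates, day = seq_len(L),
      distance_m = mets[, "distance_m"],
      duration_hr = mets[, "duration_hr"],
      n_recesses = mets[, "n_recesses"],
      nest_alive = nest_alive, female_alive = female_alive,
      flagged = flagged)
  }
  if (!length(rows)) stop("no nests with usable fixes")
  day_table <- do.call(rbind, rows)
  rownames(day_table) <- NULL
  if (!is.null(range_sizes)) {
    key <- paste(day_table$nest_id, day_table$date)
    m <- match(key, paste(range_sizes$nest_id, range_sizes$date))
    day_table$range_ha <- range_sizes$area_ha[m]
  }
  assemble_exposure(day_table, min_days = min_days)
}

#' Screen covariates for collinearity
#'
#' Computes pairwise Pearson correlations and drops, from each pair with
#' `|r|` at or above the threshold, the member listed later in the priority
#' order.
#'
#' @param data data.frame holding the candidate columns.
#' @param candidates candidate covariate names.
#' @param threshold absolute correlation at which a pair is flagged.
#' @param priority retention order; defaults to the order of `candidates`.
#' @return list of class `covariate_screen`: `r` (correlation matrix),
#'   `flagged` (data.frame of offending pairs), `dropped`, `kept`.
#' @export
screen_collinearity <- function(data, candidates, threshold = 0.7,
                                priority = candidates) {
  stopifnot(length(candidates) >= 2)
  x <- data[, candidates, drop = FALSE]
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 complete rows")
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0))
    stop("zero-variance covariate: ",
         paste(candidates[sds == 0], collapse = ", "))
  r <- cor(x)
  flagged <- data.frame(var1 = character(), var2 = character(), r = numeric())
  dropped <- character()
  cmb <- which(upper.tri(r), arr.ind = TRUE)
  for (k in seq_len(nrow(cmb))) {
    i <- cmb[k, 1]; j <- cmb[k, 2]
    if (abs(r[i, j]) >= threshold) {
      v1 <- candidates[i]; v2 <- candidates[j]
      flagged <- rbind(flagged,
                       data.frame(var1 = v1, var2 = v2, r = r[i, j]))
      loser <- if (match(v1, priority) <= match(v2, priority)) v2 else v1
      dropped <- union(dropped, loser)
    }
  }
  structure(list(r = r, flagged = flagged, dropped = dropped,
                 kept = setdiff(candidates, dropped),
                 threshold = threshold),
            class = "covariate_screen")
}

#' @export
print.covariate_screen <- function(x, ...) {
  cat("Collinearity screen (|r| >=", x$threshold, ")\n")
  print(round(x$r, 3))
  if (length(x$dropped)) {
    cat("dropped:", paste(x$dropped, collapse = ", "), "\n")
  } else cat("nothing dropped\n")
  invisible(x)
}
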