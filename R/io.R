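# Plain-CSV schemas binding the pipeline stages.  All timestamps are
# ISO-8601 local time ("YYYY-MM-DD HH:MM:SS"); all coordinates are planar
# meters.

FIX_COLS <- c("bird_id", "timestamp", "x", "y")
NEST_COLS <- c("nest_id", "bird_id", "site", "year", "attempt", "onset",
               "termination", "nest_fate", "female_fate", "nest_x", "nest_y",
               "concealment_cm")

stop_schema <- function(...) {
  stop(structure(class = c("schema_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_cols <- function(df, cols, what, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_schema("schema error in ", what, " file ", path,
                ": missing column(s) ", paste(miss, collapse = ", "))
}

#' Read a GPS fix CSV
#'
#' Expects columns `bird_id`, `timestamp` (ISO-8601), `x`, `y`.
#' @param path CSV path.
#' @return data.frame with parsed POSIXct timestamps, sorted by bird and
#'   time.
#' @export
read_fix_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, FIX_COLS, "fix", path)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  if (anyNA(df$timestamp))
    stop_schema("schema error in fix file ", path, ": unparseable timestamp")
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)))
    stop_schema("schema error in fix file ", path, ": non-finite coordinates")
  df[order(df$bird_id, df$timestamp), FIX_COLS]
}

#' Write a GPS fix CSV
#' @param fixes fix data.frame; @param path output path.
#' @export
write_fix_csv <- function(fixes, path) {
  out <- fixes[, FIX_COLS]
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a nest record CSV
#' @param path CSV path.
#' @return data.frame with parsed onset/termination dates.
#' @export
read_nest_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, NEST_COLS, "nest", path)
  df$onset <- as.Date(df$onset)
  df$termination <- as.Date(df$termination)
  if (anyNA(df$onset) || anyNA(df$termination))
    stop_schema("schema error in nest file ", path, ": unparseable date")
  bad <- which(df$onset > df$termination)
  if (length(bad))
    stop_schema("schema error in nest file ", path, ": onset after termination in row ",
                bad[1])
  if (!all(df$attempt %in% 1:4))
    stop_schema("schema error in nest file ", path, ": attempt must be 1-4")
  df
}

#' Write a nest record CSV
#' @param nests nest data.frame; @param path output path.
#' @export
write_nest_csv <- function(nests, path) {
  out <- nests[, NEST_COLS]
  out$onset <- format(as.Date(out$onset))
  out$termination <- format(as.Date(out$termination))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read an exposure-day CSV
#' @param exposure exposure data.frame; @param path CSV path.
#' @export
write_exposure_csv <- function(exposure, path) {
  out <- exposure
  out$date <- format(as.Date(out$date))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exposure_csv
#' @export
read_exposure_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("nest_id", "day", "nage", "nest_alive", "female_alive")
  check_cols(df, need, "exposure", path)
  df$date <- as.Date(df$date)
  df
}

#' Write pooled MCMC draws as CSV (one column per parameter plus `chain`)
#' @param fit a [fit_survival()] result; @param path CSV path.
#' @export
write_draws_csv <- function(fit, path) {
  rows <- lapply(seq_along(fit$chains), function(ch)
    cbind(data.frame(chain = ch), as.data.frame(fit$chains[[ch]],
                                                check.names = FALSE)))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_draws_csv
#' @param check.names passed to `read.csv` (parameter names contain `(` and
#'   `:`; they are preserved verbatim).
#' @export
read_draws_csv <- function(path, check.names = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = check.names)
  if (!"chain" %in% names(df))
    stop_schema("schema error in draws file ", path, ": missing chain column")
  df
}
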