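# Small reporting helpers for study-level counts.

#' Percentage of a count, rounded as printed in reports
#'
#' @param k count; @param n total; @param digits decimal places.
#' @return `100 * k / n` rounded to `digits`.
#' @export
percent_of <- function(k, n, digits = 0) round(100 * k / n, digits)

#' Day span of a nesting season
#'
#' @param first first onset date; @param last last termination date.
#' @return number of days from the first onset to the last termination
#'   (date difference, the convention used when a season from 18 March to
#'   20 July is reported as spanning 124 days).
#' @export
season_span <- function(first, last) {
  as.integer(as.Date(last) - as.Date(first))
}

#' Outcome summary of a nest table
#'
#' Counts and percentages of hatched nests and depredated females, plus the
#' incubation season span.
#'
#' @param nests nest table with `nest_id`, `bird_id`, `nest_fate`,
#'   `female_fate`, `onset`, `termination`.
#' @return list of counts, percentages and the season span in days.
#' @export
nest_outcome_summary <- function(nests) {
  n_nests <- nrow(nests)
  n_birds <- length(unique(nests$bird_id))
  n_hatched <- sum(nests$nest_fate == "hatched")
  dep_birds <- unique(nests$bird_id[nests$female_fate == "depredated"])
  list(n_nests = n_nests, n_birds = n_birds,
       n_hatched = n_hatched,
       pct_hatched = percent_of(n_hatched, n_nests),
       n_females_depredated = length(dep_birds),
       pct_females_depredated = percent_of(length(dep_birds), n_birds),
       season_span_days = {
         # pool years: the season is defined by day-of-year bounds
         doy <- function(d) as.integer(format(as.Date(d), "%j"))
         max(doy(nests$termination)) - min(doy(nests$onset))
       })
}
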