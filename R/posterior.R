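# Posterior summarization and decision statistics: quantile tables, highest
# density intervals, probability of direction, period survival and per-SD
# odds ratios.

#' Probability of direction
#'
#' The posterior probability that a parameter is strictly positive or
#' strictly negative, whichever is larger; draws exactly at zero are split
#' evenly between the two signs. Ranges from 0.5 (no directional evidence)
#' to 1; values of 0.9 or more are flagged as biologically significant.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @return numeric pd in \[0.5, 1\], with attribute `significant` (pd >= 0.9).
#' @export
pd <- function(draws) {
  check_draws(draws)
  half_zero <- 0.5 * mean(draws == 0)
  p <- max(mean(draws > 0) + half_zero, mean(draws < 0) + half_zero)
  attr(p, "significant") <- p >= 0.9
  p
}

check_draws <- function(draws) {
  if (length(draws) < 100) stop("need at least 100 draws")
  if (!all(is.finite(draws))) stop("non-finite draws")
  invisible(TRUE)
}

#' Highest density interval
#'
#' The shortest contiguous interval containing `mass` of the sample: the
#' minimum-length window of `ceiling(mass * n)` sorted draws.
#'
#' @param draws numeric posterior draws.
#' @param mass interval mass in (0, 1).
#' @return numeric length-2 `(low, high)`.
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m + 1L)
  width <- x[starts + m - 1L] - x[starts]
  i <- which.min(width)
  c(x[i], x[i + m - 1L])
}

#' Summarize posterior draws
#'
#' One summary row in the reporting format of the survival tables: empirical
#' quantiles at 0.025, 0.25, 0.5, 0.75, 0.975 (linear interpolation), the
#' mean, the 95% HDI and the probability of direction.
#'
#' @param draws numeric vector of at least 100 draws.
#' @param hdi_mass HDI mass.
#' @return one-row data.frame with columns `q0.025`, `q0.250`, `q0.500`,
#'   `q0.750`, `q0.975`, `mean`, `hdi_low`, `hdi_high`, `pd`.
#' @export
summarize_draws <- function(draws, hdi_mass = 0.95) {
  check_draws(draws)
  q <- quantile(draws, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE,
                type = 7)
  h <- hdi(draws, hdi_mass)
  data.frame(q0.025 = q[1], q0.250 = q[2], q0.500 = q[3], q0.750 = q[4],
             q0.975 = q[5], mean = mean(draws), hdi_low = h[1],
             hdi_high = h[2], pd = as.numeric(pd(draws)))
}

#' Period survival from daily survival draws
#'
#' Expands daily survival over the full incubation cycle: each draw is
#' raised to the power `n_days`.
#'
#' @param daily_draws posterior draws of daily survival, in (0, 1\].
#' @param n_days incubation cycle length (days).
#' @return draws of period survival.
#' @export
period_survival <- function(daily_draws, n_days = 30) {
  stopifnot(all(daily_draws > 0), all(daily_draws <= 1))
  daily_draws^n_days
}

#' Per-SD odds ratio with direction
#'
#' For a logit-scale coefficient per standardized unit, the odds ratio
#' `exp(|beta|)` together with the direction of the effect: survival is
#' `exp(|beta|)` times more likely (beta > 0) or less likely (beta < 0) per
#' one-SD increase in the covariate.
#'
#' @param beta logit-scale coefficient summary (e.g. posterior median).
#' @return list with `odds_ratio` and `direction` (`"more likely"`,
#'   `"less likely"`, or `"no effect"`).
#' @export
odds_ratio_per_sd <- function(beta) {
  direction <- if (beta > 0) "more likely" else if (beta < 0) "less likely"
    else "no effect"
  list(odds_ratio = exp(abs(beta)), direction = direction)
}

#' Posterior summary table for a fitted survival model
#'
#' One row per fixed-effect coefficient (and the intercept) in the reporting
#' format of the daily-survival tables: quantile columns 0.025/0.250/0.500/
#' 0.750/0.975 plus mean, 95% HDI, pd and the per-SD odds ratio from the
#' posterior median.
#'
#' @param fit a [fit_survival()] result.
#' @return data.frame, one row per parameter.
#' @export
posterior_table <- function(fit) {
  pars <- c("(Intercept)", fit$design$fixed)
  rows <- lapply(pars, function(pp) {
    s <- summarize_draws(posterior_draws(fit, pp))
    or <- odds_ratio_per_sd(s$q0.500)
    cbind(data.frame(parameter = pp), s,
          data.frame(odds_ratio = or$odds_ratio, direction = or$direction))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Daily and period survival summaries from a fit
#'
#' Daily survival draws are the exposure-averaged inverse-logit linear
#' predictor (see [averaged_survival_draws()]); period survival raises each
#' draw to the cycle length.
#'
#' @param fit a [fit_survival()] result (typically the intercept-only fit on
#'   the unfiltered period dataset).
#' @param n_days incubation cycle length.
#' @return list with `daily` and `period` summary rows ([summarize_draws()])
#'   and the underlying `daily_draws`.
#' @export
survival_rates <- function(fit, n_days = 30) {
  pooled <- do.call(rbind, fit$raw_chains)
  daily <- averaged_survival_draws(pooled, fit$X)
  list(daily = summarize_draws(daily),
       period = summarize_draws(period_survival(daily, n_days)),
       daily_draws = daily)
}

#' Predicted period-survival curve over one covariate
#'
#' For each standardized grid value of the focal covariate, applies the
#' inverse logit to `intercept + beta * grid` per draw (other covariates at
#' their mean, i.e. 0 standardized; random effects at 0), raises to the
#' cycle length, and summarizes to a mean and equal-tailed 95% band.
#'
#' @param fit a [fit_survival()] result.
#' @param covariate coefficient name, e.g. `"duration"`.
#' @param grid standardized covariate values.
#' @param n_days incubation cycle length.
#' @param baseline optional numeric vector of logit-scale baseline draws to
#'   use in place of the recentered intercept draws (e.g. the logit of
#'   exposure-averaged daily survival, which stays stable when sparse
#'   random-effect levels drift).
#' @return data.frame with `grid`, `raw` (grid back-transformed to raw units
#'   when scaling info is available), `mean`, `lo`, `hi`.
#' @export
predicted_period_curve <- function(fit, covariate, grid = seq(-2, 2, 0.1),
                                   n_days = 30, baseline = NULL) {
  b0 <- if (is.null(baseline)) posterior_draws(fit, "(Intercept)") else baseline
  bb <- posterior_draws(fit, covariate)
  stopifnot(length(b0) == length(bb))
  out <- vapply(grid, function(g) {
    per <- plogis(b0 + bb * g)^n_days
    c(mean(per), quantile(per, c(0.025, 0.975), names = FALSE))
  }, numeric(3))
  raw <- grid
  cv_col <- fit$spec$covariates[covariate]
  if (!is.null(fit$design$center) && !is.na(cv_col) &&
      cv_col %in% names(fit$design$center))
    raw <- grid * fit$design$scale[cv_col] + fit$design$center[cv_col]
  data.frame(grid = grid, raw = raw, mean = out[1, ], lo = out[2, ],
             hi = out[3, ])
}
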