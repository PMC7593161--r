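# Pipeline commands binding the stages into a reproducible analysis:
# simulate -> metrics (+ daily ranges, collinearity screen) -> fit ->
# summarize.  Every command writes plain CSV plus a JSON manifest echoing
# the full configuration and the provenance of each setting.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    n_birds = 40L, n_sites = 8L, years = 2014:2018, incubation_days = 30L,
    censor_rate = 0.086, renest_prob = 0.5,
    buffer_m = 27.5,
    dbbmm_window = 7L, dbbmm_margin = 3L, location_error_m = 20,
    ud_level = 0.99, grid_cell_m = 10, integration_steps = 15L,
    compute_range = TRUE,
    collinearity_threshold = 0.7,
    include_nest_legs = FALSE, night_fix_weight = 1,
    min_days = 3L, min_coverage = 0.5,
    standardize = TRUE,
    nest_chains = 3L, nest_iter = 4000L, nest_burn_in = 1000L,
    nest_thin = 3L,
    female_chains = 3L, female_iter = 7000L, female_burn_in = 2000L,
    female_thin = 3L,
    rhat_limit = 1.1)
}

#' Pipeline configuration
#'
#' Merges user overrides into the default configuration. Defaults mirror
#' the analysis protocol the package implements: 27.5 m nest buffer; dBBMM
#' window 7, margin 3, location error 20 m; 99% utilization contours;
#' collinearity threshold 0.7; nest MCMC 3 chains x 4,000 iterations
#' (burn-in 1,000, thin 3); female MCMC 7,000 iterations (burn-in 2,000).
#' The provenance of every value (`"default"` or `"user"`) is recorded and
#' echoed into each command's manifest.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `pipeline_config` with attribute `source`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  user <- list(...)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown configuration field(s): ",
                        paste(bad, collapse = ", "))
  src <- setNames(rep("default", length(cfg)), names(cfg))
  for (nm in names(user)) {
    cfg[[nm]] <- user[[nm]]
    src[nm] <- "user"
  }
  attr(cfg, "source") <- src
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys override [pipeline_config()] defaults.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

pipeline_log <- function(...) message("[nestrecess] ", sprintf(...))

unclass_config <- function(config) {
  x <- unclass(config)
  attr(x, "source") <- NULL
  x
}

write_manifest <- function(config, dir, stage, extra = list()) {
  man <- c(list(stage = stage,
                config = unclass_config(config),
                config_source = as.list(attr(config, "source"))),
           extra)
  path <- file.path(dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a dataset and write it to disk
#'
#' Wraps [make_dataset()]: writes `fixes.csv`, `nests.csv`, `truth.csv` and
#' a manifest echoing the seed and every parameter.
#'
#' @param config a [pipeline_config()].
#' @param dir output directory (created if needed).
#' @return the dataset, invisibly.
#' @export
cmd_simulate <- function(config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  params <- sim_params(n_birds = config$n_birds, n_sites = config$n_sites,
                       years = config$years,
                       incubation_days = config$incubation_days,
                       censor_rate = config$censor_rate,
                       renest_prob = config$renest_prob,
                       buffer_m = config$buffer_m,
                       seed = config$seed)
  pipeline_log("simulating %d birds with seed %d", params$n_birds,
               params$seed)
  ds <- make_dataset(params)
  write_fix_csv(ds$fixes, file.path(dir, "fixes.csv"))
  write_nest_csv(ds$nests, file.path(dir, "nests.csv"))
  tr <- ds$truth
  tr$date <- format(tr$date)
  write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  write_manifest(config, dir, "simulate",
                 list(n_nests = nrow(ds$nests), n_fixes = nrow(ds$fixes)))
  invisible(ds)
}

#' Compute metrics, daily ranges and the exposure tables
#'
#' Reads the fix and nest CSVs, optionally computes dBBMM daily range
#' sizes, builds the covariate and period exposure tables, runs the
#' collinearity screen, and writes `exposure_covariate.csv`,
#' `exposure_period.csv`, `range_sizes.csv` and a manifest including the
#' correlation matrix and any dropped covariates.
#'
#' @param config a [pipeline_config()].
#' @param dir directory holding `fixes.csv` and `nests.csv`; outputs are
#'   written alongside.
#' @return list with the exposure tables and the screen, invisibly.
#' @export
cmd_metrics <- function(config, dir) {
  fixes <- read_fix_csv(file.path(dir, "fixes.csv"))
  nests <- read_nest_csv(file.path(dir, "nests.csv"))
  ranges <- NULL
  if (isTRUE(config$compute_range)) {
    pipeline_log("computing dBBMM daily ranges for %d nests", nrow(nests))
    ranges <- range_sizes_for_nests(nests, fixes,
                                    window = config$dbbmm_window,
                                    margin = config$dbbmm_margin,
                                    delta = config$location_error_m,
                                    cell_m = config$grid_cell_m,
                                    n_steps = config$integration_steps,
                                    level = config$ud_level)
    write.csv(ranges, file.path(dir, "range_sizes.csv"), row.names = FALSE)
  }
  exp_tabs <- build_exposure_table(nests, fixes, range_sizes = ranges,
                                   buffer_m = config$buffer_m,
                                   min_days = config$min_days,
                                   min_coverage = config$min_coverage,
                                   include_nest_legs = config$include_nest_legs,
                                   night_fix_weight = config$night_fix_weight)
  candidates <- c("attempt", "concealment_cm", "distance_m", "duration_hr",
                  "n_recesses")
  if (!is.null(ranges)) candidates <- c(candidates, "range_ha")
  screen <- screen_collinearity(exp_tabs$covariate, candidates,
                                threshold = config$collinearity_threshold)
  if (length(screen$dropped))
    pipeline_log("collinearity screen dropped: %s",
                 paste(screen$dropped, collapse = ", "))
  write_exposure_csv(exp_tabs$covariate,
                     file.path(dir, "exposure_covariate.csv"))
  write_exposure_csv(exp_tabs$period, file.path(dir, "exposure_period.csv"))
  write_manifest(config, dir, "metrics",
                 list(n_covariate_rows = nrow(exp_tabs$covariate),
                      n_period_rows = nrow(exp_tabs$period),
                      correlations = as.data.frame(round(screen$r, 4)),
                      dropped_covariates = screen$dropped))
  invisible(list(exposure = exp_tabs, screen = screen, ranges = ranges))
}

fit_one_model <- function(config, dir, outcome) {
  cov_tab <- read_exposure_csv(file.path(dir, "exposure_covariate.csv"))
  per_tab <- read_exposure_csv(file.path(dir, "exposure_period.csv"))
  if (nrow(cov_tab) == 0) stop("empty exposure table")
  cfgv <- function(f) config[[paste0(outcome, "_", f)]]
  cfg <- mcmc_config(outcome, n_chains = cfgv("chains"),
                     n_iter = cfgv("iter"), burn_in = cfgv("burn_in"),
                     thin = cfgv("thin"), seed = config$seed)
  spec <- model_spec(outcome)
  pipeline_log("fitting %s model: %d chains x %d iterations", outcome,
               cfg$n_chains, cfg$n_iter)
  fit <- fit_survival(cov_tab, spec, cfg,
                      standardize = isTRUE(config$standardize))
  spec0 <- model_spec(outcome, covariates = character(0))
  fit0 <- fit_survival(per_tab, spec0, cfg)
  write_draws_csv(fit, file.path(dir, paste0("draws_", outcome, ".csv")))
  write_draws_csv(fit0, file.path(dir, paste0("draws_", outcome,
                                              "_period.csv")))
  write_manifest(config, dir, paste0("fit_", outcome),
                 list(chains = cfg$n_chains, iterations = cfg$n_iter,
                      burn_in = cfg$burn_in, thin = cfg$thin,
                      rhat = as.list(round(fit$rhat, 4)),
                      rhat_period = as.list(round(fit0$rhat, 4)),
                      exposure_days = fit$design$n))
  list(fit = fit, period_fit = fit0)
}

#' Fit the daily survival models
#'
#' Fits the requested model(s) with the configured MCMC settings: the
#' covariate model on the short-nest-censored exposure table and an
#' intercept-only model on the unfiltered period table. Draws are written
#' as CSV, and the manifest records the settings and all R-hat values.
#'
#' @param config a [pipeline_config()].
#' @param dir directory holding the exposure CSVs.
#' @param model `"nest"`, `"female"` or `"both"`.
#' @return list of fits, invisibly.
#' @export
cmd_fit <- function(config, dir, model = c("both", "nest", "female")) {
  model <- match.arg(model)
  outcomes <- if (model == "both") c("nest", "female") else model
  fits <- lapply(outcomes, function(oc) fit_one_model(config, dir, oc))
  names(fits) <- outcomes
  invisible(fits)
}

draws_to_chains <- function(df) {
  lapply(split(df[setdiff(names(df), "chain")], df$chain), as.matrix)
}

summarize_draws_file <- function(path, rhat_limit, force) {
  df <- read_draws_csv(path)
  chains <- draws_to_chains(df)
  rhat <- gelman_rubin(chains)
  if (any(rhat >= rhat_limit) && !force)
    stop(structure(class = c("convergence_refusal", "error", "condition"),
                   list(message = sprintf(
                     "refusing to summarize %s: max R-hat %.3f >= %.2f (rerun with force = TRUE to override)",
                     basename(path), max(rhat), rhat_limit), call = NULL)))
  pooled <- do.call(rbind, chains)
  rows <- lapply(colnames(pooled), function(pp) {
    cbind(data.frame(parameter = pp), summarize_draws(pooled[, pp]))
  })
  list(table = do.call(rbind, rows), pooled = pooled, rhat = rhat)
}

#' Summarize fitted models into report tables
#'
#' Reads the draws CSVs, refuses to summarize any model whose R-hat reaches
#' the configured limit (unless forced), and writes per-model summary
#' tables in the quantile/pd reporting format, daily and period survival
#' estimates from the intercept-only fits, and predicted period-survival
#' curves over the duration covariate.
#'
#' @param config a [pipeline_config()].
#' @param dir directory holding the draws CSVs.
#' @param model `"nest"`, `"female"` or `"both"`.
#' @param force summarize even when R-hat exceeds the limit.
#' @return list of summary tables, invisibly.
#' @export
cmd_summarize <- function(config, dir, model = c("both", "nest", "female"),
                          force = FALSE) {
  model <- match.arg(model)
  outcomes <- if (model == "both") c("nest", "female") else model
  out <- list()
  for (oc in outcomes) {
    s <- summarize_draws_file(file.path(dir, paste0("draws_", oc, ".csv")),
                              config$rhat_limit, force)
    fixed <- !grepl("^year:|^site:|Intercept", s$table$parameter)
    sig <- s$table$parameter[s$table$pd >= 0.9 & fixed]
    if (length(sig))
      pipeline_log("%s model: pd >= 0.9 for %s", oc,
                   paste(sig, collapse = ", "))
    write.csv(s$table, file.path(dir, paste0("summary_", oc, ".csv")),
              row.names = FALSE)
    p <- summarize_draws_file(file.path(dir, paste0("draws_", oc,
                                                    "_period.csv")),
                              config$rhat_limit, force)
    # recentering shifts lie along flat likelihood directions, so the
    # linear predictors (and hence averaged survival) are unchanged by it
    per_tab <- read_exposure_csv(file.path(dir, "exposure_period.csv"))
    des0 <- build_design(per_tab, model_spec(oc, covariates = character(0)))
    daily <- averaged_survival_draws(
      p$pooled[, des0$param_names, drop = FALSE], des0$X)
    rates <- rbind(cbind(data.frame(quantity = "daily_survival"),
                         summarize_draws(daily)),
                   cbind(data.frame(quantity = "period_survival"),
                         summarize_draws(period_survival(
                           daily, config$incubation_days))))
    write.csv(rates, file.path(dir, paste0("survival_", oc, ".csv")),
              row.names = FALSE)
    if ("duration" %in% colnames(s$pooled) &&
        nrow(s$pooled) == length(daily)) {
      grid <- seq(-2, 2, 0.1)
      # baseline: logit of the exposure-averaged daily survival, stable
      # under random-effect-level drift in sparse site-year cells
      b0 <- qlogis(pmin(pmax(daily, 1e-12), 1 - 1e-12))
      bb <- s$pooled[, "duration"]
      curve <- t(vapply(grid, function(g) {
        per <- plogis(b0 + bb * g)^config$incubation_days
        c(mean(per), quantile(per, c(0.025, 0.975), names = FALSE))
      }, numeric(3)))
      curve_df <- data.frame(grid = grid, mean = curve[, 1],
                             lo = curve[, 2], hi = curve[, 3])
      write.csv(curve_df, file.path(dir, paste0("curve_", oc,
                                                "_duration.csv")),
                row.names = FALSE)
    }
    out[[oc]] <- list(table = s$table, rates = rates, rhat = s$rhat)
  }
  write_manifest(config, dir, "summarize", list())
  invisible(out)
}

#' Run the full pipeline from one seed
#'
#' `simulate` -> `metrics` -> `fit` -> `summarize` in one directory; the
#' whole chain is deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()]; @param dir working directory.
#' @return the summary list from [cmd_summarize()], invisibly.
#' @export
cmd_run_all <- function(config, dir) {
  cmd_simulate(config, dir)
  cmd_metrics(config, dir)
  cmd_fit(config, dir)
  cmd_summarize(config, dir)
}
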