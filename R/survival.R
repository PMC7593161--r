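# Bayesian hierarchical daily survival models for nests and incubating
# females.  One exposure day is one Bernoulli trial: the probability that a
# nest (female) alive on day j is still alive on day j+1 is inverse-logit of
# a linear predictor in standardized covariates plus year and
# site-within-year random intercepts.  Every coefficient and random-effect
# level carries an independent Normal(mean 0, precision 0.001) prior.

#' Specify a daily survival model
#'
#' The nest model uses covariates (attempt, conceal, distance, duration,
#' recess, nage); the female model drops nest age. Year and site-within-year
#' random intercepts are included by default; every level has its own
#' Normal(0, precision 0.001) prior with no variance hyperprior.
#'
#' @param outcome `"nest"` or `"female"`.
#' @param covariates named character vector mapping coefficient names to
#'   exposure-table columns; `character(0)` gives the intercept-only model
#'   used for period survival. `NULL` selects the default set.
#' @param random_effects include year and site-within-year intercepts.
#' @param prior_precision precision of the Normal prior on all parameters.
#' @return object of class `survival_model_spec`.
#' @export
model_spec <- function(outcome = c("nest", "female"), covariates = NULL,
                       random_effects = TRUE, prior_precision = 0.001) {
  outcome <- match.arg(outcome)
  if (is.null(covariates)) {
    covariates <- c(attempt = "attempt", conceal = "concealment_cm",
                    distance = "distance_m", duration = "duration_hr",
                    recess = "n_recesses")
    if (outcome == "nest") covariates <- c(covariates, nage = "nage")
  }
  structure(list(outcome = outcome,
                 response = paste0(outcome, "_alive"),
                 covariates = covariates,
                 random_effects = isTRUE(random_effects),
                 prior_precision = prior_precision),
            class = "survival_model_spec")
}

#' MCMC settings for the survival models
#'
#' Defaults are 3 chains with 4,000 iterations, burn-in 1,000 and thinning 3
#' for the nest model, and 7,000 iterations with burn-in 2,000 for the
#' female model. Proposal scales adapt only during burn-in, targeting an
#' acceptance rate between `target_accept[1]` and `target_accept[2]`.
#'
#' @param model `"nest"` or `"female"` (sets iteration defaults).
#' @param n_chains,n_iter,burn_in,thin standard MCMC controls.
#' @param seed integer; chain c uses `seed + c - 1`.
#' @param adapt_interval iterations between proposal-scale updates.
#' @param target_accept length-2 acceptance-rate window.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(model = c("nest", "female"), n_chains = 3,
                        n_iter = NULL, burn_in = NULL, thin = 3, seed = 1,
                        adapt_interval = 50, target_accept = c(0.30, 0.45)) {
  model <- match.arg(model)
  if (is.null(n_iter)) n_iter <- if (model == "nest") 4000L else 7000L
  if (is.null(burn_in)) burn_in <- if (model == "nest") 1000L else 2000L
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 1)
  structure(list(model = model, n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 target_accept = target_accept),
            class = "mcmc_config")
}

#' Z-score covariate columns
#'
#' Replaces each column by (x - mean)/SD and records the centers and scales,
#' so that a one-unit change in a standardized covariate is a one-SD change
#' on the raw scale (the scale on which per-SD odds ratios are reported).
#'
#' @param data exposure data.frame.
#' @param cols columns to standardize.
#' @return `data` with standardized columns and attributes `center` and
#'   `scale` (named numeric vectors).
#' @export
standardize_covariates <- function(data, cols) {
  ctr <- scl <- setNames(numeric(length(cols)), cols)
  for (cc in cols) {
    x <- data[[cc]]
    ctr[cc] <- mean(x, na.rm = TRUE)
    scl[cc] <- sd(x, na.rm = TRUE)
    if (!is.finite(scl[cc]) || scl[cc] == 0)
      stop("covariate has zero standard deviation: ", cc)
    data[[cc]] <- (x - ctr[cc]) / scl[cc]
  }
  attr(data, "center") <- ctr
  attr(data, "scale") <- scl
  data
}

# Design matrix: intercept, standardized covariates, one indicator column
# per year level and per (site, year) level.  Returns grouping metadata for
# the sum-to-zero reporting convention.
build_design <- function(data, spec, standardize = TRUE) {
  y <- data[[spec$response]]
  if (is.null(y)) stop("response column ", spec$response, " not found")
  keep <- rep(TRUE, nrow(data))
  for (cc in spec$covariates) keep <- keep & is.finite(data[[cc]])
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  center <- scale_ <- NULL
  Z <- NULL
  if (length(spec$covariates)) {
    if (standardize) {
      data <- standardize_covariates(data, unname(spec$covariates))
      center <- attr(data, "center"); scale_ <- attr(data, "scale")
    }
    Z <- as.matrix(data[, unname(spec$covariates), drop = FALSE])
    colnames(Z) <- names(spec$covariates)
  }
  X <- cbind(`(Intercept)` = rep(1, nrow(data)))
  if (!is.null(Z)) X <- cbind(X, Z)
  year_cols <- site_cols <- character()
  site_year <- character()
  if (spec$random_effects) {
    yl <- sort(unique(data$year))
    Y <- sapply(yl, function(v) as.numeric(data$year == v))
    colnames(Y) <- paste0("year:", yl)
    year_cols <- colnames(Y)
    sy <- unique(data.frame(site = data$site, year = data$year))
    sy <- sy[order(sy$year, sy$site), , drop = FALSE]
    S <- sapply(seq_len(nrow(sy)), function(k)
      as.numeric(data$site == sy$site[k] & data$year == sy$year[k]))
    colnames(S) <- paste0("site:", sy$site, ":", sy$year)
    site_cols <- colnames(S)
    site_year <- paste0("year:", sy$year)
    X <- cbind(X, Y, S)
  }
  list(X = X, y = as.numeric(y),
       param_names = colnames(X),
       fixed = names(spec$covariates),
       year_cols = year_cols, site_cols = site_cols, site_year = site_year,
       center = center, scale = scale_, n = nrow(data))
}

#' Log posterior of a daily survival model
#'
#' Bernoulli log likelihood with logit link plus the Normal(0,
#' `prior_prec`) log prior over every parameter (normalizing constants
#' included).
#'
#' @param params numeric parameter vector matching the columns of `X`.
#' @param X design matrix; @param y 0/1 outcome vector.
#' @param prior_prec prior precision.
#' @return scalar log posterior density.
#' @export
log_posterior <- function(params, X, y, prior_prec = 0.001) {
  if (!all(is.finite(X))) stop("non-finite values in the design matrix")
  stopifnot(length(params) == ncol(X), length(y) == nrow(X))
  eta <- drop(X %*% params)
  ll <- sum(y * eta - log1pexp(eta))
  lp <- sum(dnorm(params, 0, sqrt(1 / prior_prec), log = TRUE))
  ll + lp
}

log1pexp <- function(x) {
  out <- numeric(length(x))
  hi <- x > 35; lo <- x < -35; mid <- !hi & !lo
  out[hi] <- x[hi]
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out
}

#' Run the adaptive Metropolis-within-Gibbs sampler
#'
#' Componentwise Gaussian random-walk proposals with burn-in-only scale
#' adaptation; chains are initialized from dispersed standard-normal draws
#' (the prior scaled to SD 1) and are fully reproducible given the seed.
#'
#' @param X design matrix; @param y 0/1 outcomes.
#' @param config an [mcmc_config()].
#' @param prior_prec prior precision on all parameters.
#' @param param_names optional parameter names.
#' @param groups optional list of integer vectors (1-based column indices;
#'   first element parent, rest children) describing flat likelihood
#'   directions of hierarchical intercept structures; along each, a shift is
#'   Gibbs-sampled exactly from its Gaussian (prior-only) full conditional
#'   after every sweep, which removes the slow ridge mixing that
#'   unconstrained level-plus-intercept parameterizations otherwise suffer.
#' @return object of class `mcmc_chains`: list with `chains` (list of
#'   draw matrices, post burn-in and thinning), `param_names`, `acceptance`,
#'   `config`.
#' @export
run_mcmc <- function(X, y, config, prior_prec = 0.001,
                     param_names = colnames(X), groups = list()) {
  stopifnot(nrow(X) > 0, inherits(config, "mcmc_config"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  p <- ncol(X)
  groups0 <- lapply(groups, function(g) as.integer(g) - 1L)
  chains <- vector("list", config$n_chains)
  acc <- matrix(NA_real_, config$n_chains, p)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    init <- rnorm(p)
    res <- mwg_chain_cpp(X, y, prior_prec, config$n_iter, config$burn_in,
                         config$thin, init, rep(0.5, p),
                         config$adapt_interval,
                         config$target_accept[1], config$target_accept[2],
                         groups0)
    colnames(res$draws) <- param_names
    chains[[ch]] <- res$draws
    acc[ch, ] <- res$acceptance
  }
  structure(list(chains = chains, param_names = param_names,
                 acceptance = acc, config = config),
            class = "mcmc_chains")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes R-hat per parameter from between- and within-chain variances,
#' with the (n-1)/n finite-sample correction; values near 1 indicate
#' converged, well-mixed chains.
#'
#' @param chains an `mcmc_chains` object or a list of equal-size draw
#'   matrices (rows = draws, columns = parameters).
#' @return named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "mcmc_chains")) chains <- chains$chains
  m <- length(chains)
  if (m < 2) stop("R-hat needs at least 2 chains")
  n <- nrow(chains[[1]])
  if (n < 10) stop("R-hat needs at least 10 draws per chain")
  p <- ncol(chains[[1]])
  rhat <- setNames(numeric(p), colnames(chains[[1]]))
  for (j in seq_len(p)) {
    draws <- sapply(chains, function(ch) ch[, j])
    W <- mean(apply(draws, 2, stats::var))
    B_over_n <- stats::var(colMeans(draws))
    if (W <= 0) { rhat[j] <- 1; next }
    var_plus <- (n - 1) / n * W + B_over_n
    rhat[j] <- sqrt(var_plus / W)
  }
  rhat
}

# Flat likelihood directions of the intercept/year/site hierarchy, as
# 1-based column-index groups (parent first).
design_groups <- function(des) {
  groups <- list()
  nm <- des$param_names
  int_i <- match("(Intercept)", nm)
  if (length(des$year_cols)) {
    groups[[length(groups) + 1L]] <- c(int_i, match(des$year_cols, nm))
    for (yc in unique(des$site_year)) {
      sc <- des$site_cols[des$site_year == yc]
      if (length(sc))
        groups[[length(groups) + 1L]] <- c(match(yc, nm), match(sc, nm))
    }
  } else if (length(des$site_cols)) {
    groups[[length(groups) + 1L]] <- c(int_i, match(des$site_cols, nm))
  }
  groups
}

# Sum-to-zero reporting convention: per draw, pool the mean of the
# site-within-year levels into their year level, then the mean of the year
# levels into the intercept.  Sampling itself is unconstrained.
recenter_chains <- function(chains, design) {
  lapply(chains, function(ch) {
    if (length(design$site_cols)) {
      for (yc in unique(design$site_year)) {
        sc <- design$site_cols[design$site_year == yc]
        mu <- rowMeans(ch[, sc, drop = FALSE])
        ch[, sc] <- ch[, sc, drop = FALSE] - mu
        if (yc %in% colnames(ch)) ch[, yc] <- ch[, yc] + mu
        else ch[, "(Intercept)"] <- ch[, "(Intercept)"] + mu
      }
    }
    if (length(design$year_cols)) {
      mu <- rowMeans(ch[, design$year_cols, drop = FALSE])
      ch[, design$year_cols] <- ch[, design$year_cols, drop = FALSE] - mu
      ch[, "(Intercept)"] <- ch[, "(Intercept)"] + mu
    }
    ch
  })
}

#' Fit a daily survival model by MCMC
#'
#' Standardizes the covariates, builds the design (intercept, covariates,
#' year and site-within-year indicator columns), runs the sampler, computes
#' R-hat, and applies the sum-to-zero reporting convention to the
#' random-effect levels (their means are pooled into the intercept for
#' reporting; sampling is unconstrained).
#'
#' @param data exposure-day data.frame (one row per nest- or female-day).
#' @param spec a [model_spec()]; @param config an [mcmc_config()].
#' @param standardize z-score the covariates (default) or fit on raw scale.
#' @return object of class `daily_survival_fit` with elements `chains`
#'   (recentered), `raw_chains`, `rhat`, `design` metadata, `spec`,
#'   `config`, `acceptance`.
#' @export
fit_survival <- function(data, spec, config = mcmc_config(spec$outcome),
                         standardize = TRUE) {
  stopifnot(inherits(spec, "survival_model_spec"))
  if (nrow(data) == 0) stop("empty exposure table")
  des <- build_design(data, spec, standardize = standardize)
  groups <- design_groups(des)
  fit <- run_mcmc(des$X, des$y, config, prior_prec = spec$prior_precision,
                  groups = groups)
  rhat <- if (config$n_chains >= 2) gelman_rubin(fit) else NULL
  chains <- recenter_chains(fit$chains, des)
  structure(list(chains = chains, raw_chains = fit$chains,
                 param_names = fit$param_names, rhat = rhat,
                 design = des[c("param_names", "fixed", "year_cols",
                                "site_cols", "site_year", "center",
                                "scale", "n")],
                 X = des$X, y = des$y,
                 spec = spec, config = config,
                 acceptance = fit$acceptance),
            class = "daily_survival_fit")
}

# Collapse a design matrix to its unique rows with exposure weights.
collapse_design <- function(X) {
  key <- apply(X, 1, paste, collapse = "\r")
  ui <- !duplicated(key)
  Xu <- X[ui, , drop = FALSE]
  w <- as.vector(table(factor(key, levels = key[ui])))
  list(X = Xu, w = w / sum(w))
}

#' Posterior draws of exposure-averaged daily survival
#'
#' For each posterior draw, the mean over all exposure days of the
#' inverse-logit linear predictor: the average daily survival the monitored
#' population actually experienced. Averaging over the observed exposure
#' composition (rather than reading survival off the intercept alone) keeps
#' the estimate meaningful when sparse site-year cells with no deaths let
#' individual random-effect levels drift under their near-flat priors.
#'
#' @param draws matrix of posterior draws (columns named as the design).
#' @param X design matrix of the exposure days.
#' @return numeric vector, one averaged daily survival per draw.
#' @export
averaged_survival_draws <- function(draws, X) {
  stopifnot(ncol(draws) == ncol(X))
  cd <- collapse_design(X)
  eta <- draws %*% t(cd$X)
  drop(plogis(eta) %*% cd$w)
}

#' Pooled posterior draws of one parameter
#'
#' @param fit a [fit_survival()] result.
#' @param param parameter name (e.g. `"(Intercept)"`, `"duration"`).
#' @param recentered use the sum-to-zero-recentered chains (default).
#' @return numeric vector of pooled post-burn-in, thinned draws.
#' @export
posterior_draws <- function(fit, param, recentered = TRUE) {
  ch <- if (recentered) fit$chains else fit$raw_chains
  if (!param %in% colnames(ch[[1]])) stop("unknown parameter: ", param)
  unlist(lapply(ch, function(m) m[, param]), use.names = FALSE)
}

#' @export
print.daily_survival_fit <- function(x, ...) {
  cat(sprintf("Daily %s survival fit: %d exposure days, %d parameters, %d chains x %d kept draws\n",
              x$spec$outcome, x$design$n, length(x$param_names),
              length(x$chains), nrow(x$chains[[1]])))
  if (!is.null(x$rhat))
    cat(sprintf("  max R-hat %.3f\n", max(x$rhat)))
  invisible(x)
}
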