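#' @keywords internal
"_PACKAGE"

## Canonical scalar parameter names used by the tornado, the PSA and
## scenario overrides.  Vector blocks (mRS distribution, RRs, HRs,
## utilities) are addressed by indexed names (mrs0..mrs6, rr0..rr6, ...).
.cost_fields <- c("drug_price_per_mg", "acute_mrs01", "acute_mrs25",
                  "acute_death", "sich_cost", "annual_post_mrs01",
                  "annual_post_mrs25", "recurrent_stroke_cost",
                  "infusion_first_hour", "infusion_additional_hour")

.prob_fields <- c("p_sich_argatroban", "p_sich_control",
                  "annual_recurrence", "recurrence_case_fatality")

#' Load a model parameter set from a YAML configuration file
#'
#' Reads a configuration mirroring the published input table (mRS
#' distribution, risk ratios, event probabilities, hazard ratios, background
#' mortality bands, utilities, costs, settings), validates every invariant
#' (probabilities in \[0,1\], distribution summing to one, contiguous
#' mortality bands, `low <= value <= high` for every ranged entry) and
#' returns a `cea_params` object.
#'
#' Missing optional settings fall back to the package defaults
#' (`discount_rate = 0.05`, `start_age = 66`, `horizon_years = 30`,
#' `cycle_length = 0.25`, WTP thresholds 89,358 / 268,074 CNY per QALY).
#'
#' @param path Path to a YAML file; defaults to the bundled
#'   `default_ease_china.yaml` holding the published base-case inputs.
#' @return An object of class `cea_params`: a list with elements
#'   `mrs_control`, `rr`, `hr` (numeric vectors), `mortality`
#'   (data.frame `age_low`, `age_high`, `annual_probability`),
#'   `utilities` (length 7, dead = 0), `u_recurrence`, `sich_disutility`,
#'   scalar probabilities, `costs` (named list), `discount_rate`,
#'   `start_age`, `horizon_years`, `cycle_length`, `wtp_1x`, `wtp_3x`,
#'   and `ranges`, a data.frame of (parameter, low, high, family) driving
#'   the sensitivity analyses.
#' @seealso [default_parameters()], [save_parameters()]
#' @export
load_parameters <- function(path = system.file("extdata",
                                               "default_ease_china.yaml",
                                               package = "strokeCEA")) {
  if (!file.exists(path))
    stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)

  need <- c("mrs_distribution", "risk_ratios", "probabilities",
            "hazard_ratios", "mortality_table", "utilities", "costs")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("configuration error: missing required key(s): ",
         paste(missing, collapse = ", "))

  getv <- function(block, key, what = "value") {
    ent <- block[[key]]
    if (is.null(ent))
      stop("configuration error: missing required key: ", key)
    if (is.list(ent)) {
      v <- ent[[what]]
      if (is.null(v)) {
        if (what == "value")
          stop("configuration error: key '", key, "' has no value")
        v <- ent[["value"]]  # degenerate range: low = high = value
      }
      v
    } else {
      if (what == "value") ent else ent  # bare scalar: zero-width range
    }
  }
  vec <- function(block, prefix, k, what = "value")
    vapply(paste0(prefix, 0:(k - 1)), function(nm) as.numeric(getv(block, nm, what)),
           numeric(1))

  mrs  <- vec(cfg$mrs_distribution, "mrs", 7)
  rr   <- vec(cfg$risk_ratios, "rr", 7)
  hr   <- vec(cfg$hazard_ratios, "hr", 6)
  u    <- c(vec(cfg$utilities, "u", 6), 0)  # dead state utility fixed at 0
  names(u) <- paste0("u", 0:6)

  mort <- do.call(rbind, lapply(cfg$mortality_table, function(b)
    data.frame(age_low = as.numeric(b$age_low),
               age_high = as.numeric(b$age_high),
               annual_probability = as.numeric(b$annual_probability))))
  mort <- mort[order(mort$age_low), , drop = FALSE]
  rownames(mort) <- NULL

  costs <- lapply(.cost_fields, function(nm) as.numeric(getv(cfg$costs, nm)))
  names(costs) <- .cost_fields

  settings <- if (is.null(cfg$settings)) list() else cfg$settings
  setv <- function(key, default) {
    if (is.null(settings[[key]])) default
    else if (is.list(settings[[key]])) as.numeric(settings[[key]]$value)
    else as.numeric(settings[[key]])
  }

  params <- structure(list(
    mrs_control = stats::setNames(mrs, paste0("mrs", 0:6)),
    rr          = stats::setNames(rr, paste0("rr", 0:6)),
    hr          = stats::setNames(hr, paste0("hr", 0:5)),
    mortality   = mort,
    utilities   = u,
    u_recurrence    = as.numeric(getv(cfg$utilities, "u_recurrence")),
    sich_disutility = as.numeric(getv(cfg$utilities, "sich_disutility")),
    p_sich_argatroban = as.numeric(getv(cfg$probabilities, "p_sich_argatroban")),
    p_sich_control    = as.numeric(getv(cfg$probabilities, "p_sich_control")),
    annual_recurrence = as.numeric(getv(cfg$probabilities, "annual_recurrence")),
    recurrence_case_fatality =
      as.numeric(getv(cfg$probabilities, "recurrence_case_fatality")),
    costs = costs,
    drug_price_max = if (is.null(cfg$costs$drug_price_max)) NA_real_
                     else as.numeric(cfg$costs$drug_price_max),
    discount_rate = setv("discount_rate", 0.05),
    start_age     = setv("start_age", 66),
    horizon_years = setv("horizon_years", 30),
    cycle_length  = setv("cycle_length", 0.25),
    wtp_1x        = setv("wtp_1x", 89358),
    wtp_3x        = setv("wtp_3x", 268074)
  ), class = "cea_params")

  params$ranges <- .build_ranges(cfg, params)
  validate_parameters(params)
  params
}

#' The published base-case parameter set
#'
#' Convenience wrapper for [load_parameters()] on the bundled
#' `default_ease_china.yaml`.
#' @return A validated `cea_params` object.
#' @export
default_parameters <- function() load_parameters()

## Collect (parameter, low, high, family) rows for every ranged input.
.build_ranges <- function(cfg, params) {
  rowf <- function(block, key, name, family) {
    ent <- block[[key]]
    lo <- hi <- NA_real_
    if (is.list(ent)) {
      lo <- if (is.null(ent$low)) as.numeric(ent$value) else as.numeric(ent$low)
      hi <- if (is.null(ent$high)) as.numeric(ent$value) else as.numeric(ent$high)
    } else lo <- hi <- as.numeric(ent)
    data.frame(parameter = name, low = lo, high = hi, family = family)
  }
  out <- list()
  for (i in 0:6) out[[length(out) + 1L]] <-
    rowf(cfg$mrs_distribution, paste0("mrs", i), paste0("mrs", i), "dirichlet")
  for (i in 0:6) out[[length(out) + 1L]] <-
    rowf(cfg$risk_ratios, paste0("rr", i), paste0("rr", i), "lognormal")
  for (nm in .prob_fields) out[[length(out) + 1L]] <-
    rowf(cfg$probabilities, nm, nm, "beta")
  for (i in 0:5) out[[length(out) + 1L]] <-
    rowf(cfg$hazard_ratios, paste0("hr", i), paste0("hr", i), "lognormal")
  for (i in 0:5) out[[length(out) + 1L]] <-
    rowf(cfg$utilities, paste0("u", i), paste0("u", i), "beta")
  out[[length(out) + 1L]] <- rowf(cfg$utilities, "u_recurrence",
                                  "u_recurrence", "beta")
  out[[length(out) + 1L]] <- rowf(cfg$utilities, "sich_disutility",
                                  "sich_disutility", "beta")
  for (nm in .cost_fields) out[[length(out) + 1L]] <-
    rowf(cfg$costs, nm, nm, "gamma")
  dr <- if (is.null(cfg$settings$discount_rate)) list(value = 0.05)
        else cfg$settings$discount_rate
  out[[length(out) + 1L]] <- rowf(list(discount_rate = dr), "discount_rate",
                                  "discount_rate", "fixed")
  ranges <- do.call(rbind, out)
  rownames(ranges) <- NULL
  ranges
}

#' Validate a parameter set
#'
#' Checks every structural invariant and stops with a message naming the
#' offending field on the first violation.  Called by [load_parameters()];
#' exported so programmatically modified sets can be re-checked.
#'
#' @param params A `cea_params` object.
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  chk <- function(ok, field, msg)
    if (!all(ok)) stop("validation error in '", field, "': ", msg)

  p <- params
  chk(abs(sum(p$mrs_control) - 1) < 1e-9, "mrs_distribution",
      "probabilities must sum to 1")
  chk(p$mrs_control >= 0 & p$mrs_control <= 1, "mrs_distribution",
      "entries must lie in [0,1]")
  chk(p$rr > 0, "risk_ratios", "risk ratios must be strictly positive")
  chk(p$hr > 0, "hazard_ratios", "hazard ratios must be strictly positive")
  for (nm in .prob_fields)
    chk(p[[nm]] >= 0 && p[[nm]] <= 1, nm, "must be a probability in [0,1]")
  chk(p$utilities >= 0 & p$utilities <= 1, "utilities", "must lie in [0,1]")
  chk(p$utilities[7] == 0, "utilities", "dead-state utility must be 0")
  chk(p$u_recurrence >= 0 && p$u_recurrence <= 1, "u_recurrence",
      "must lie in [0,1]")
  chk(p$sich_disutility >= 0 && p$sich_disutility <= 1, "sich_disutility",
      "must lie in [0,1]")
  chk(unlist(p$costs) >= 0, "costs", "costs must be non-negative")
  chk(p$discount_rate >= 0 && p$discount_rate <= 0.2, "discount_rate",
      "must lie in [0, 0.2]")
  n_cycles <- p$horizon_years / p$cycle_length
  chk(abs(n_cycles - round(n_cycles)) < 1e-9, "horizon_years",
      "must be an integer number of cycles")

  m <- p$mortality
  chk(nrow(m) >= 1, "mortality_table", "must have at least one band")
  chk(m$annual_probability >= 0 & m$annual_probability <= 1,
      "mortality_table", "probabilities must lie in [0,1]")
  if (nrow(m) > 1)
    chk(abs(m$age_high[-nrow(m)] - m$age_low[-1]) < 1e-9, "mortality_table",
        "bands must be contiguous and non-overlapping")
  chk(m$age_low[1] <= p$start_age, "mortality_table",
      sprintf("first band starts at %g but cohort starts at age %g",
              m$age_low[1], p$start_age))
  chk(is.infinite(m$age_high[nrow(m)]) ||
        m$age_high[nrow(m)] >= p$start_age + p$horizon_years,
      "mortality_table", "bands must cover the whole simulated horizon")

  rng <- p$ranges
  bad <- !(rng$low <= .get_param_values(p, rng$parameter) + 1e-12 &
             .get_param_values(p, rng$parameter) <= rng$high + 1e-12)
  if (any(bad))
    stop("validation error in '", rng$parameter[which(bad)[1]],
         "': range must satisfy low <= value <= high")
  invisible(params)
}

#' Save a parameter set to YAML
#'
#' Writes a configuration file that [load_parameters()] reads back to an
#' identical `cea_params` object (value round trip is exact).
#'
#' @param params A `cea_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  rng <- params$ranges
  ent <- function(name, value) {
    i <- match(name, rng$parameter)
    if (!is.na(i) && (rng$low[i] != value || rng$high[i] != value))
      list(value = value, low = rng$low[i], high = rng$high[i])
    else list(value = value)
  }
  block <- function(prefix, values)
    stats::setNames(lapply(seq_along(values) - 1L, function(i)
      ent(paste0(prefix, i), unname(values[i + 1L]))),
      paste0(prefix, seq_along(values) - 1L))
  cfg <- list(
    mrs_distribution = block("mrs", params$mrs_control),
    risk_ratios = block("rr", params$rr),
    probabilities = stats::setNames(
      lapply(.prob_fields, function(nm) ent(nm, params[[nm]])), .prob_fields),
    hazard_ratios = block("hr", params$hr),
    mortality_table = lapply(seq_len(nrow(params$mortality)), function(i)
      as.list(params$mortality[i, ])),
    utilities = c(block("u", params$utilities[1:6]),
                  list(u_recurrence = ent("u_recurrence", params$u_recurrence),
                       sich_disutility = ent("sich_disutility",
                                             params$sich_disutility))),
    costs = c(stats::setNames(
      lapply(.cost_fields, function(nm) ent(nm, params$costs[[nm]])),
      .cost_fields),
      if (!is.na(params$drug_price_max))
        list(drug_price_max = params$drug_price_max)),
    settings = list(
      discount_rate = ent("discount_rate", params$discount_rate),
      start_age = params$start_age,
      horizon_years = params$horizon_years,
      cycle_length = params$cycle_length,
      wtp_1x = params$wtp_1x,
      wtp_3x = params$wtp_3x)
  )
  writeLines(yaml::as.yaml(cfg, precision = 15), path)
  invisible(path)
}

#' @export
print.cea_params <- function(x, ...) {
  cat("Cost-effectiveness model parameters (cea_params)\n")
  cat(sprintf("  start age %g, horizon %g y, cycle %g y (%d Markov cycles)\n",
              x$start_age, x$horizon_years, x$cycle_length,
              as.integer(round(x$horizon_years / x$cycle_length)) - 1L))
  cat(sprintf("  discount rate %.3f; WTP %s / %s CNY per QALY\n",
              x$discount_rate, format(x$wtp_1x, big.mark = ","),
              format(x$wtp_3x, big.mark = ",")))
  cat("  control mRS distribution:",
      paste(sprintf("%.3f", x$mrs_control), collapse = " "), "\n")
  cat("  risk ratios (argatroban):",
      paste(sprintf("%.2f", x$rr), collapse = " "), "\n")
  cat(sprintf("  drug price %.3f CNY/mg; annual recurrence %.3f\n",
              x$costs$drug_price_per_mg, x$annual_recurrence))
  invisible(x)
}

## --- parameter addressing -------------------------------------------------

## Fetch current point values for canonical parameter names (vectorized).
.get_param_values <- function(params, names) {
  vapply(names, function(nm) .get_param(params, nm), numeric(1))
}

.get_param <- function(params, name) {
  if (grepl("^mrs[0-6]$", name))
    return(unname(params$mrs_control[as.integer(substring(name, 4)) + 1L]))
  if (grepl("^rr[0-6]$", name))
    return(unname(params$rr[as.integer(substring(name, 3)) + 1L]))
  if (grepl("^hr[0-5]$", name))
    return(unname(params$hr[as.integer(substring(name, 3)) + 1L]))
  if (grepl("^u[0-5]$", name))
    return(unname(params$utilities[as.integer(substring(name, 2)) + 1L]))
  if (name %in% .cost_fields) return(params$costs[[name]])
  if (name %in% c(.prob_fields, "u_recurrence", "sich_disutility",
                  "discount_rate", "start_age", "horizon_years",
                  "wtp_1x", "wtp_3x"))
    return(params[[name]])
  stop("unknown parameter: ", name)
}

#' Set one model parameter by name
#'
#' Addresses any scalar input by its canonical name (`rr0`..`rr6`,
#' `hr0`..`hr5`, `u0`..`u5`, `mrs0`..`mrs6`, `u_recurrence`,
#' `sich_disutility`, the event probabilities, the cost fields,
#' `discount_rate`, `start_age`, `horizon_years`).  Setting an `mrs*`
#' category renormalizes the whole distribution to sum to one.
#'
#' @param params A `cea_params` object.
#' @param name Canonical parameter name.
#' @param value New value.
#' @param validate Re-run [validate_parameters()] (default `FALSE`; the
#'   sensitivity analyses intentionally push values to range endpoints).
#' @return The modified `cea_params` object.
#' @export
set_param <- function(params, name, value, validate = FALSE) {
  if (grepl("^mrs[0-6]$", name)) {
    i <- as.integer(substring(name, 4)) + 1L
    params$mrs_control[i] <- value
    params$mrs_control <- params$mrs_control / sum(params$mrs_control)
  } else if (grepl("^rr[0-6]$", name)) {
    params$rr[as.integer(substring(name, 3)) + 1L] <- value
  } else if (grepl("^hr[0-5]$", name)) {
    params$hr[as.integer(substring(name, 3)) + 1L] <- value
  } else if (grepl("^u[0-5]$", name)) {
    params$utilities[as.integer(substring(name, 2)) + 1L] <- value
  } else if (name %in% .cost_fields) {
    params$costs[[name]] <- value
  } else if (name %in% c(.prob_fields, "u_recurrence", "sich_disutility",
                         "discount_rate", "start_age", "horizon_years",
                         "wtp_1x", "wtp_3x")) {
    params[[name]] <- value
  } else stop("unknown parameter: ", name)
  if (validate) validate_parameters(params)
  params
}

## --- distribution fitting from published summaries ------------------------

.fitted <- function(family, par, point, low, high)
  structure(list(family = family, par = par, source_point = point,
                 source_low = low, source_high = high),
            class = "fitted_dist")

#' Fit a beta distribution from a point estimate and a 95\% range
#'
#' Moment matching: mean = `point`, sd = `(high - low)/3.92` (the range is
#' read as a 95\% interval).  A zero-width range yields a point mass.  Means
#' at the \[0,1\] boundary are clamped to `[1e-6, 1 - 1e-6]` before matching
#' so inputs whose range touches 0 (e.g. sICH probabilities) remain fittable.
#'
#' @param point,low,high Point estimate and range, all in \[0,1\].
#' @return A `fitted_dist` with family `"beta"` (parameters `shape1`,
#'   `shape2`) or `"point"`.
#' @export
fit_beta_from_summary <- function(point, low, high) {
  if (any(c(point, low, high) < 0) || any(c(point, low, high) > 1) ||
      low > point || point > high)
    stop("fit_beta_from_summary: need 0 <= low <= point <= high <= 1")
  if (high == low)
    return(.fitted("point", c(value = point), point, low, high))
  s <- (high - low) / 3.92
  m <- min(max(point, 1e-6), 1 - 1e-6)
  ## sd cannot exceed the Bernoulli bound sqrt(m(1-m)); cap just inside it
  s <- min(s, 0.99 * sqrt(m * (1 - m)))
  nu <- m * (1 - m) / s^2 - 1
  .fitted("beta", c(shape1 = m * nu, shape2 = (1 - m) * nu),
          point, low, high)
}

#' Fit a gamma distribution from a point estimate and a 95\% range
#'
#' Moment matching: mean = `point`, sd = `(high - low)/3.92`, so
#' `shape = (mean/sd)^2`, `scale = sd^2/mean`.
#'
#' @param point,low,high Point estimate (> 0) and bracketing range.
#' @return A `fitted_dist` with family `"gamma"` (parameters `shape`,
#'   `scale`) or `"point"` for a zero-width range.
#' @export
fit_gamma_from_summary <- function(point, low, high) {
  if (point <= 0 || low > point || point > high)
    stop("fit_gamma_from_summary: need 0 < point and low <= point <= high")
  if (high == low)
    return(.fitted("point", c(value = point), point, low, high))
  s <- (high - low) / 3.92
  .fitted("gamma", c(shape = (point / s)^2, scale = s^2 / point),
          point, low, high)
}

#' Fit a lognormal distribution from a ratio and its 95\% CI
#'
#' Median-preserving fit on the log scale: `meanlog = log(point)`,
#' `sdlog = (log(high) - log(low))/3.92`.  Used for risk ratios and
#' hazard ratios.
#'
#' @param point,low,high Ratio point estimate and CI bounds, all > 0.
#' @return A `fitted_dist` with family `"lognormal"` (parameters `meanlog`,
#'   `sdlog`) or `"point"` for a zero-width CI.
#' @export
fit_lognormal_from_ci <- function(point, low, high) {
  if (any(c(point, low, high) <= 0))
    stop("fit_lognormal_from_ci: inputs must be strictly positive")
  if (low > point || point > high)
    stop("fit_lognormal_from_ci: need low <= point <= high")
  if (high == low)
    return(.fitted("point", c(value = point), point, low, high))
  .fitted("lognormal",
          c(meanlog = log(point), sdlog = (log(high) - log(low)) / 3.92),
          point, low, high)
}

#' Fit a Dirichlet distribution from a probability vector and ranges
#'
#' The Dirichlet mean equals `dist`; the single concentration budget is the
#' across-category average of the implied multinomial sample size
#' `n_i = m_i (1 - m_i) / sd_i^2` with `sd_i = (high_i - low_i)/3.92`
#' (zero-width categories are excluded from the average).  Alphas are
#' `m_i * n_eff`.
#'
#' @param dist Probability vector summing to 1.
#' @param low,high Per-category range bounds bracketing `dist`.
#' @return A `fitted_dist` with family `"dirichlet"` (parameter vector
#'   `alpha`, attribute-free) whose marginal means equal `dist`.
#' @export
fit_dirichlet_from_ranges <- function(dist, low, high) {
  if (abs(sum(dist) - 1) > 1e-9)
    stop("fit_dirichlet_from_ranges: dist must sum to 1")
  if (any(low > dist + 1e-12) || any(dist > high + 1e-12))
    stop("fit_dirichlet_from_ranges: ranges must bracket the point values")
  sd <- (high - low) / 3.92
  ok <- sd > 0 & dist > 0 & dist < 1
  if (!any(ok))
    return(.fitted("point", c(value = dist), dist, low, high))
  n_eff <- mean(dist[ok] * (1 - dist[ok]) / sd[ok]^2)
  .fitted("dirichlet", stats::setNames(dist * n_eff,
                                       paste0("alpha", seq_along(dist) - 1L)),
          dist, low, high)
}

#' @export
print.fitted_dist <- function(x, ...) {
  cat(sprintf("fitted_dist: %s (%s)\n", x$family,
              paste(sprintf("%s=%.6g", names(x$par), x$par), collapse = ", ")))
  invisible(x)
}

#' Analytic mean of a fitted distribution
#' @param fd A `fitted_dist`.
#' @return The mean (vector-valued for Dirichlet).
#' @export
dist_mean <- function(fd) {
  switch(fd$family,
    point = unname(fd$par),
    beta = unname(fd$par["shape1"] / (fd$par["shape1"] + fd$par["shape2"])),
    gamma = unname(fd$par["shape"] * fd$par["scale"]),
    lognormal = unname(exp(fd$par["meanlog"] + fd$par["sdlog"]^2 / 2)),
    dirichlet = unname(fd$par / sum(fd$par)))
}

#' Analytic standard deviation of a fitted distribution
#' @param fd A `fitted_dist`.
#' @return The sd (per-component marginal sd for Dirichlet).
#' @export
dist_sd <- function(fd) {
  switch(fd$family,
    point = 0 * unname(fd$par),
    beta = {
      a <- fd$par["shape1"]; b <- fd$par["shape2"]
      unname(sqrt(a * b / ((a + b)^2 * (a + b + 1))))
    },
    gamma = unname(sqrt(fd$par["shape"]) * fd$par["scale"]),
    lognormal = {
      m <- exp(fd$par["meanlog"] + fd$par["sdlog"]^2 / 2)
      unname(m * sqrt(exp(fd$par["sdlog"]^2) - 1))
    },
    dirichlet = {
      a0 <- sum(fd$par); m <- fd$par / a0
      unname(sqrt(m * (1 - m) / (a0 + 1)))
    })
}

#' Draw from a fitted distribution
#' @param fd A `fitted_dist`.
#' @param n Number of draws.
#' @return Numeric vector of length `n` (matrix `n` x k for Dirichlet).
#' @export
draw_fitted <- function(fd, n = 1) {
  switch(fd$family,
    point = if (length(fd$par) > 1)
      matrix(rep(unname(fd$par), each = n), nrow = n)
      else rep(unname(fd$par), n),
    beta = stats::rbeta(n, fd$par["shape1"], fd$par["shape2"]),
    gamma = stats::rgamma(n, shape = fd$par["shape"], scale = fd$par["scale"]),
    lognormal = stats::rlnorm(n, fd$par["meanlog"], fd$par["sdlog"]),
    dirichlet = {
      g <- matrix(stats::rgamma(n * length(fd$par),
                                shape = rep(fd$par, each = n)), nrow = n)
      g / rowSums(g)
    })
}

#' Fit every PSA distribution for a parameter set
#'
#' Family assignment: costs are gamma; scalar probabilities, utilities and
#' the recurrence case fatality are beta; risk ratios and hazard ratios are
#' lognormal (the printed range read as a 95\% CI); the control mRS
#' distribution is Dirichlet.  Background mortality and the discount rate
#' carry no published uncertainty distribution and stay fixed.
#'
#' @param params A `cea_params` object.
#' @return Named list of `fitted_dist` objects keyed by canonical parameter
#'   name, plus element `mrs_distribution` for the Dirichlet.
#' @export
fit_psa_distributions <- function(params) {
  rng <- params$ranges
  fits <- list()
  mrs_rows <- rng[rng$family == "dirichlet", ]
  fits$mrs_distribution <- fit_dirichlet_from_ranges(
    unname(params$mrs_control), mrs_rows$low, mrs_rows$high)
  for (i in which(rng$family != "dirichlet")) {
    nm <- rng$parameter[i]
    pt <- .get_param(params, nm)
    fits[[nm]] <- switch(rng$family[i],
      beta = fit_beta_from_summary(pt, rng$low[i], rng$high[i]),
      gamma = fit_gamma_from_summary(pt, rng$low[i], rng$high[i]),
      lognormal = fit_lognormal_from_ci(pt, rng$low[i], rng$high[i]),
      fixed = .fitted("point", c(value = pt), pt, rng$low[i], rng$high[i]))
  }
  fits
}

#' Export fitted PSA distributions as a table
#'
#' @param params A `cea_params` object.
#' @param path Optional CSV path; when given the table is written there.
#' @return A data.frame (parameter, family, par1, par2) where the Dirichlet
#'   appears as one row per category with `par1` = alpha.
#' @export
export_psa_distributions <- function(params, path = NULL) {
  fits <- fit_psa_distributions(params)
  rows <- list()
  for (nm in names(fits)) {
    fd <- fits[[nm]]
    if (fd$family == "dirichlet") {
      for (j in seq_along(fd$par))
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = paste0("mrs", j - 1L), family = "dirichlet",
          par1 = unname(fd$par[j]), par2 = NA_real_)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, family = fd$family,
        par1 = unname(fd$par[1]),
        par2 = if (length(fd$par) > 1) unname(fd$par[2]) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
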