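#' Simulate a two-arm trial with mRS and sICH outcomes
#'
#' Generates the summary data structure the model consumes: multinomial
#' 3-month mRS counts per arm (treatment probabilities are the
#' risk-ratio-weighted control distribution) and binomial sICH counts.
#'
#' @param true_control Length-7 control-arm mRS probability vector.
#' @param true_rr Length-7 risk-ratio vector.
#' @param n_per_arm Patients per arm.
#' @param p_sich Length-2 sICH probabilities `c(argatroban, control)`.
#' @param seed Integer seed; fixed seed reproduces counts exactly.
#' @return An object of class `synthetic_trial`: per-arm `n`, `mrs_counts`
#'   (2x7 matrix, rows argatroban/control), `sich_counts`, and the true
#'   generating parameters.
#' @export
simulate_trial <- function(true_control, true_rr, n_per_arm,
                           p_sich = c(argatroban = 0.009, control = 0.007),
                           seed = 1) {
  stopifnot(length(true_control) == 7, length(true_rr) == 7,
            n_per_arm >= 1, length(p_sich) == 2)
  true_treat <- c(unclass(apply_rr(true_control, true_rr)))
  set.seed(seed)
  counts <- rbind(
    argatroban = as.vector(stats::rmultinom(1, n_per_arm, true_treat)),
    control = as.vector(stats::rmultinom(1, n_per_arm, true_control)))
  colnames(counts) <- paste0("mrs", 0:6)
  sich <- c(argatroban = stats::rbinom(1, n_per_arm, p_sich[1]),
            control = stats::rbinom(1, n_per_arm, p_sich[2]))
  structure(list(n_per_arm = n_per_arm, mrs_counts = counts,
                 sich_counts = sich,
                 true_control = true_control, true_rr = true_rr,
                 true_p_sich = p_sich, seed = seed),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("Synthetic two-arm trial: n = %d per arm (seed %d)\n",
              x$n_per_arm, x$seed))
  print(x$mrs_counts)
  cat("sICH counts:", paste(names(x$sich_counts), x$sich_counts,
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Estimate model inputs from a simulated trial
#'
#' Reconstructs the summary inputs the model consumes from raw counts:
#' control mRS proportions with normal-approximation 95\% ranges, per-
#' category risk ratios with log-scale delta-method 95\% CIs, and sICH
#' proportions with 95\% ranges.  Categories with a zero cell in either
#' arm receive the Haldane-Anscombe continuity correction (0.5 added to
#' all four cells of that category's 2x2) and are flagged.
#'
#' @param trial A `synthetic_trial`.
#' @return List with `mrs_control` (data.frame value/low/high),
#'   `rr` (data.frame value/low/high/corrected), and `p_sich`
#'   (data.frame arm/value/low/high).
#' @export
estimate_parameters <- function(trial) {
  n <- trial$n_per_arm
  ct <- trial$mrs_counts["control", ]
  tx <- trial$mrs_counts["argatroban", ]

  p_ct <- ct / n
  se_ct <- sqrt(pmax(p_ct * (1 - p_ct), 0) / n)
  mrs_control <- data.frame(
    category = 0:6, value = as.vector(p_ct),
    low = pmax(0, p_ct - 1.96 * se_ct),
    high = pmin(1, p_ct + 1.96 * se_ct))

  corrected <- (ct == 0 | tx == 0 | ct == n | tx == n)
  a <- ifelse(corrected, tx + 0.5, tx)      # treatment events
  b <- ifelse(corrected, n - tx + 0.5, n - tx)
  c_ <- ifelse(corrected, ct + 0.5, ct)     # control events
  d <- ifelse(corrected, n - ct + 0.5, n - ct)
  n_tx <- a + b; n_ct <- c_ + d
  rr_hat <- (a / n_tx) / (c_ / n_ct)
  se_log <- sqrt(1 / a - 1 / n_tx + 1 / c_ - 1 / n_ct)
  rr <- data.frame(
    category = 0:6, value = as.vector(rr_hat),
    low = as.vector(exp(log(rr_hat) - 1.96 * se_log)),
    high = as.vector(exp(log(rr_hat) + 1.96 * se_log)),
    corrected = as.vector(corrected))

  p_s <- trial$sich_counts / n
  se_s <- sqrt(pmax(p_s * (1 - p_s), 0) / n)
  p_sich <- data.frame(arm = names(trial$sich_counts),
                       value = as.vector(p_s),
                       low = pmax(0, p_s - 1.96 * se_s),
                       high = pmin(1, p_s + 1.96 * se_s))
  rownames(p_sich) <- NULL

  list(mrs_control = mrs_control, rr = rr, p_sich = p_sich)
}

#' Build a parameter set from trial estimates
#'
#' Replaces the trial-derived blocks (control mRS distribution, risk
#' ratios, sICH probabilities, with their estimated ranges) of a base
#' parameter set, normalizing the estimated control distribution.
#'
#' @param trial A `synthetic_trial`.
#' @param base A `cea_params` to inherit every non-trial input from.
#' @return A validated `cea_params`.
#' @export
parameters_from_trial <- function(trial, base = default_parameters()) {
  est <- estimate_parameters(trial)
  p <- base
  d <- est$mrs_control$value
  p$mrs_control[] <- d / sum(d)
  p$rr[] <- est$rr$value
  p$p_sich_argatroban <- est$p_sich$value[est$p_sich$arm == "argatroban"]
  p$p_sich_control <- est$p_sich$value[est$p_sich$arm == "control"]
  rng <- p$ranges
  for (i in 0:6) {
    rng[rng$parameter == paste0("mrs", i), c("low", "high")] <-
      c(max(0, min(est$mrs_control$low[i + 1], p$mrs_control[i + 1])),
        min(1, max(est$mrs_control$high[i + 1], p$mrs_control[i + 1])))
    rng[rng$parameter == paste0("rr", i), c("low", "high")] <-
      c(min(est$rr$low[i + 1], est$rr$value[i + 1]),
        max(est$rr$high[i + 1], est$rr$value[i + 1]))
  }
  rng[rng$parameter == "p_sich_argatroban", c("low", "high")] <-
    est$p_sich[est$p_sich$arm == "argatroban", c("low", "high")]
  rng[rng$parameter == "p_sich_control", c("low", "high")] <-
    est$p_sich[est$p_sich$arm == "control", c("low", "high")]
  p$ranges <- rng
  validate_parameters(p)
  p
}

#' Generate a random valid parameter set
#'
#' Draws a structurally valid `cea_params` for property-based testing:
#' a Dirichlet mRS distribution, lognormal risk ratios, bounded event
#' probabilities, non-increasing utilities over mRS 0-5, positive costs,
#' non-decreasing hazard ratios, and a synthetic life table with
#' age-increasing mortality.  Every generated set passes
#' [validate_parameters()] and runs end-to-end.
#'
#' @param seed Integer seed.
#' @return A validated `cea_params`.
#' @export
random_parameter_set <- function(seed = 1) {
  set.seed(seed)
  p <- default_parameters()

  g <- stats::rgamma(7, shape = 2)
  p$mrs_control[] <- g / sum(g)
  p$rr[] <- stats::rlnorm(7, 0, 0.3)
  p$hr[] <- cumprod(c(1, stats::runif(5, 1, 1.25)))
  p$p_sich_argatroban <- stats::runif(1, 0, 0.05)
  p$p_sich_control <- stats::runif(1, 0, 0.05)
  p$annual_recurrence <- stats::runif(1, 0.02, 0.3)
  p$recurrence_case_fatality <- stats::runif(1, 0.05, 0.4)
  u <- sort(stats::runif(6, 0.05, 0.98), decreasing = TRUE)
  p$utilities[1:6] <- u
  p$u_recurrence <- stats::runif(1, 0.1, u[1])
  p$sich_disutility <- stats::runif(1, 0.1, 0.5)
  for (nm in .cost_fields)
    p$costs[[nm]] <- p$costs[[nm]] * stats::rlnorm(1, 0, 0.25)
  p$discount_rate <- stats::runif(1, 0, 0.08)

  age_breaks <- seq(p$start_age, p$start_age + 25, by = 5)
  mort <- data.frame(
    age_low = age_breaks,
    age_high = c(age_breaks[-1], Inf),
    annual_probability = pmin(0.9, cumprod(
      c(stats::runif(1, 0.005, 0.03), stats::runif(5, 1.2, 1.9)))))
  p$mortality <- mort

  ## refresh ranges so low <= value <= high still holds everywhere
  rng <- p$ranges
  vals <- .get_param_values(p, rng$parameter)
  rng$low <- pmin(rng$low, vals)
  rng$high <- pmax(rng$high, vals)
  p$ranges <- rng
  validate_parameters(p)
  p
}

#' Export a synthetic trial as tabular counts and a loadable config
#'
#' Writes the trial's counts as a long CSV (arm, mrs_category, count) and,
#' optionally, a YAML parameter file (trial estimates merged into the
#' default base) consumable by [load_parameters()].
#'
#' @param trial A `synthetic_trial`.
#' @param counts_path CSV output path.
#' @param config_path Optional YAML output path.
#' @return The counts data.frame, invisibly.
#' @export
export_trial <- function(trial, counts_path, config_path = NULL) {
  counts <- data.frame(
    arm = rep(rownames(trial$mrs_counts), each = 7),
    mrs_category = rep(0:6, times = 2),
    count = c(t(trial$mrs_counts)))
  utils::write.csv(counts, counts_path, row.names = FALSE, quote = FALSE)
  if (!is.null(config_path))
    save_parameters(parameters_from_trial(trial), config_path)
  invisible(counts)
}
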