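#' Discount factor
#'
#' @param time Time in years since model start.
#' @param rate Annual discount rate.
#' @return `(1 + rate)^(-time)`; 1 at time 0.
#' @export
discount_factor <- function(time, rate) {
  if (any(rate < 0) || any(time < 0)) stop("time and rate must be >= 0")
  (1 + rate)^(-time)
}

#' Per-cycle cost, QALY and life-year accruals
#'
#' Decomposes one Markov cycle.  From the start-of-cycle occupancy and the
#' newly-recurring mass per origin state, the function derives: recurrence
#' decedents (per-event case fatality; they incur the recurrent-stroke
#' event cost but accrue no utility), recurrence survivors (redistributed
#' over equal-or-worse states, valued at the recurrence utility for the
#' cycle), and the non-recurring fraction (thinned by the per-cycle
#' non-stroke death probabilities, valued at their state utility).  Annual
#' post-hospitalization costs apply to end-of-cycle alive occupancy at one
#' quarter of the annual amount; the recurrent-stroke event cost applies
#' to the whole newly-recurred mass.
#'
#' @param occupancy Length-7 start-of-cycle occupancy (sums to 1).
#' @param new_recurrence Length-7 newly-recurred mass per origin state
#'   (entry 7 must be 0; `new_recurrence <= occupancy` element-wise).
#' @param params A `cea_params` object.
#' @param p_ns Length-6 per-cycle non-stroke death probabilities for the
#'   non-recurring fraction (default all zero).
#' @return List with `cost` (CNY), `qaly`, `ly` (years), and
#'   `end_occupancy`, the implied end-of-cycle occupancy.
#' @export
cycle_accruals <- function(occupancy, new_recurrence, params,
                           p_ns = rep(0, 6)) {
  if (any(new_recurrence > occupancy + 1e-12))
    stop("new recurrence mass exceeds occupancy")
  cyc <- params$cycle_length
  cf <- params$recurrence_case_fatality
  u <- params$utilities

  surv_rec <- numeric(7)
  for (j in 0:5)
    if (new_recurrence[j + 1L] > 0)
      surv_rec <- surv_rec +
        new_recurrence[j + 1L] * (1 - cf) * recurrence_redistribution(j)

  non_rec_alive <- (occupancy[1:6] - new_recurrence[1:6]) * (1 - p_ns)
  end_alive <- non_rec_alive + surv_rec[1:6]
  total_rec <- sum(new_recurrence)

  co <- params$costs
  cost <- cyc * (sum(end_alive[1:2]) * co$annual_post_mrs01 +
                   sum(end_alive[3:6]) * co$annual_post_mrs25) +
    total_rec * co$recurrent_stroke_cost
  qaly <- cyc * (sum(non_rec_alive * u[1:6]) +
                   total_rec * (1 - cf) * params$u_recurrence)
  ly <- cyc * sum(end_alive)

  end_occ <- c(end_alive, occupancy[7] + sum(occupancy[1:6]) - sum(end_alive))
  list(cost = cost, qaly = qaly, ly = ly, end_occupancy = end_occ)
}

#' Run the Markov cohort phase for one arm
#'
#' Propagates the acute-phase 3-month mRS distribution through quarterly
#' cycles (119 for the default 30-year horizon), rebuilding the transition
#' machinery as the cohort ages across background-mortality bands.  Cycle
#' `t` covers years `(0.25 t, 0.25 (t+1))` and is discounted at
#' `(1 + rate)^(-0.25 t)` (end-of-tree timing); the decision-tree period
#' itself is year 0 and undiscounted.  No half-cycle correction is applied.
#'
#' @param acute An `acute_phase` object ([run_decision_tree()]).
#' @param params A `cea_params` object.
#' @param n_cycles Number of Markov cycles; default
#'   `horizon_years / cycle_length - 1` (the first cycle-length is the
#'   decision tree).
#' @return An object of class `arm_result`: totals (`total_cost`,
#'   `total_qaly`, `total_ly` discounted; `undiscounted` twin list), the
#'   acute-phase contribution, and `trace`, a per-cycle data.frame with
#'   occupancy (`state0..state6`), cohort age, newly-recurred mass, and
#'   discounted/undiscounted per-cycle accruals.
#' @export
run_markov <- function(acute, params, n_cycles = NULL) {
  cyc <- params$cycle_length
  if (is.null(n_cycles))
    n_cycles <- as.integer(round(params$horizon_years / cyc)) - 1L
  occ <- c(unclass(acute$dist))

  tr_cost <- tr_qaly <- tr_ly <- tr_rec <- tr_age <- numeric(n_cycles)
  tr_occ <- matrix(0, n_cycles, 7)
  disc <- discount_factor(cyc * seq_len(n_cycles), params$discount_rate)

  comp <- NULL
  comp_age_band <- NA_real_
  for (t in seq_len(n_cycles)) {
    age <- params$start_age + t * cyc
    band <- findInterval(age, params$mortality$age_low)
    if (is.null(comp) || band != comp_age_band) {
      comp <- .cycle_components(age, params)
      comp_age_band <- band
    }
    new_rec <- c(occ[1:6] * comp$p_rec, 0)
    acc <- cycle_accruals(occ, new_rec, params, comp$p_ns)
    occ <- acc$end_occupancy
    tr_cost[t] <- acc$cost; tr_qaly[t] <- acc$qaly; tr_ly[t] <- acc$ly
    tr_rec[t] <- sum(new_rec); tr_age[t] <- age
    tr_occ[t, ] <- occ
  }

  trace <- data.frame(cycle = seq_len(n_cycles), age = tr_age,
                      tr_occ,
                      new_recurrence = tr_rec,
                      cost = tr_cost, qaly = tr_qaly, ly = tr_ly,
                      cost_disc = tr_cost * disc,
                      qaly_disc = tr_qaly * disc,
                      ly_disc = tr_ly * disc)
  names(trace)[3:9] <- paste0("state", 0:6)

  structure(list(
    arm = acute$arm,
    total_cost = acute$acute_cost + sum(trace$cost_disc),
    total_qaly = acute$acute_qaly + sum(trace$qaly_disc),
    total_ly   = acute$acute_ly + sum(trace$ly_disc),
    undiscounted = list(
      total_cost = acute$acute_cost + sum(trace$cost),
      total_qaly = acute$acute_qaly + sum(trace$qaly),
      total_ly   = acute$acute_ly + sum(trace$ly)),
    acute = acute,
    trace = trace
  ), class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm '%s': discounted cost %.0f CNY, %.3f QALY, %.3f LY\n",
              x$arm, x$total_cost, x$total_qaly, x$total_ly))
  cat(sprintf("  (undiscounted: %.0f CNY, %.3f QALY, %.3f LY; %d cycles)\n",
              x$undiscounted$total_cost, x$undiscounted$total_qaly,
              x$undiscounted$total_ly, nrow(x$trace)))
  invisible(x)
}

#' Export a cohort trace
#'
#' @param arm_result An `arm_result`.
#' @param path Optional CSV path.
#' @return Tidy data.frame (cycle, age, state, occupancy, cost, qaly, ly,
#'   cost_disc, qaly_disc, ly_disc).
#' @export
export_trace <- function(arm_result, path = NULL) {
  tr <- arm_result$trace
  long <- do.call(rbind, lapply(0:6, function(s)
    data.frame(cycle = tr$cycle, age = tr$age, state = s,
               occupancy = tr[[paste0("state", s)]],
               cost = tr$cost, qaly = tr$qaly, ly = tr$ly,
               cost_disc = tr$cost_disc, qaly_disc = tr$qaly_disc,
               ly_disc = tr$ly_disc)))
  long <- long[order(long$cycle, long$state), ]
  rownames(long) <- NULL
  if (!is.null(path))
    utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  long
}
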