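# Individual-level microsimulation used as an independent oracle for the
# cohort recursion.  Events are simulated per walker per cycle (recurrence
# -> case fatality -> redistribution; otherwise non-stroke death), and
# accruals follow the same event-level rules the cohort model integrates,
# so cohort totals must agree within Monte-Carlo error.
microsim_arm <- function(acute_dist, params, n_cycles, n_walkers, seed) {
  set.seed(seed)
  cyc <- params$cycle_length
  cf <- params$recurrence_case_fatality
  u <- params$utilities
  co <- params$costs
  annual_cost <- c(co$annual_post_mrs01, co$annual_post_mrs01,
                   rep(co$annual_post_mrs25, 4), 0)

  state <- sample.int(7, n_walkers, replace = TRUE, prob = acute_dist) - 1L
  cost <- qaly <- ly <- numeric(n_walkers)
  occupancy <- matrix(0, n_cycles, 7)

  for (t in seq_len(n_cycles)) {
    age <- params$start_age + t * cyc
    cc <- strokeCEA:::.cycle_components(age, params)
    disc <- discount_factor(t * cyc, params$discount_rate)
    alive <- state < 6L
    n_alive <- sum(alive)
    if (n_alive > 0) {
      rec <- alive & (stats::runif(n_walkers) < cc$p_rec)
      # recurrence branch
      idx_rec <- which(rec)
      if (length(idx_rec)) {
        cost[idx_rec] <- cost[idx_rec] + disc * co$recurrent_stroke_cost
        die <- stats::runif(length(idx_rec)) < cf
        idx_die <- idx_rec[die]
        idx_live <- idx_rec[!die]
        state[idx_die] <- 6L
        if (length(idx_live)) {
          new_state <- vapply(state[idx_live], function(s)
            (s:5L)[sample.int(6L - s, 1L)], integer(1))
          state[idx_live] <- new_state
          qaly[idx_live] <- qaly[idx_live] + disc * cyc * params$u_recurrence
          ly[idx_live] <- ly[idx_live] + disc * cyc
          cost[idx_live] <- cost[idx_live] +
            disc * cyc * annual_cost[new_state + 1L]
        }
      }
      # non-recurrence branch
      idx_nr <- which(alive & !rec)
      if (length(idx_nr)) {
        p_die <- cc$p_ns[state[idx_nr] + 1L]
        die <- stats::runif(length(idx_nr)) < p_die
        state[idx_nr[die]] <- 6L
        idx_surv <- idx_nr[!die]
        if (length(idx_surv)) {
          qaly[idx_surv] <- qaly[idx_surv] +
            disc * cyc * u[state[idx_surv] + 1L]
          ly[idx_surv] <- ly[idx_surv] + disc * cyc
          cost[idx_surv] <- cost[idx_surv] +
            disc * cyc * annual_cost[state[idx_surv] + 1L]
        }
      }
    }
    occupancy[t, ] <- tabulate(state + 1L, 7) / n_walkers
  }
  list(mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n_walkers),
       mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n_walkers),
       mean_ly = mean(ly), se_ly = stats::sd(ly) / sqrt(n_walkers),
       occupancy = occupancy, n = n_walkers)
}

# Base-case parameters shared across test files (cheap to build once).
base_params <- default_parameters()

# Published 3-month control-arm mRS distribution and risk ratios, used as
# literals so tests do not depend on the config file being correct.
tab_mrs <- c(0.116, 0.211, 0.175, 0.231, 0.112, 0.092, 0.063)
tab_rr <- c(1.63, 0.99, 0.92, 1.07, 0.90, 0.58, 0.64)
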