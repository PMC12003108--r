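#' Convert an annual incidence to a 3-month transition probability
#'
#' Uses the constant-rate conversion `r = -log(1 - R) / 4` followed by
#' `p = 1 - exp(-r)`, where `R` is the annual incidence, `r` the 3-month
#' event rate and `p` the per-cycle transition probability.
#'
#' @param annual_incidence Annual event probability in \[0, 1).
#' @param cycles_per_year Number of model cycles per year (default 4).
#' @return Per-cycle probability, in `[0, annual_incidence]` and monotone
#'   increasing in the input.
#' @export
annual_rate_to_cycle_prob <- function(annual_incidence, cycles_per_year = 4) {
  if (any(annual_incidence < 0) || any(annual_incidence >= 1))
    stop("annual incidence must lie in [0, 1)")
  1 - exp(log(1 - annual_incidence) / cycles_per_year)
}

#' Look up background annual mortality for an age
#'
#' Bands are half-open `[age_low, age_high)`; the last band is open-ended
#' and applies to all older ages.
#'
#' @param age Age in years.
#' @param table Mortality data.frame (`age_low`, `age_high`,
#'   `annual_probability`), as in `cea_params$mortality`.
#' @return Annual death probability of the band containing `age`.
#' @export
background_annual_mortality <- function(age, table) {
  if (age < table$age_low[1])
    stop(sprintf("age %g below mortality table coverage (starts at %g)",
                 age, table$age_low[1]))
  i <- findInterval(age, table$age_low)
  table$annual_probability[i]
}

#' Per-cycle non-stroke death probability, HR-adjusted
#'
#' The annual background probability is converted to a rate
#' (`-log(1 - P)`), multiplied by the death hazard ratio of the mRS state
#' (hazard ratios act on the rate scale), divided across the year's cycles,
#' and converted back to a probability.
#'
#' @param age Age in years at cycle start.
#' @param mrs Alive mRS state, integer 0-5.
#' @param table Mortality table (see [background_annual_mortality()]).
#' @param hr Length-6 hazard-ratio vector indexed by mRS 0-5.
#' @param cycles_per_year Cycles per year (default 4).
#' @return Per-cycle death probability in \[0, 1).
#' @export
nonstroke_death_cycle_prob <- function(age, mrs, table, hr,
                                       cycles_per_year = 4) {
  if (any(mrs < 0) || any(mrs > 5)) stop("mrs must be in 0..5")
  p_bg <- background_annual_mortality(age, table)
  unname(1 - exp(-(-log(1 - p_bg)) * hr[mrs + 1L] / cycles_per_year))
}

#' Post-recurrence redistribution over equal-or-worse states
#'
#' Survivors of a recurrent stroke are spread uniformly over the alive mRS
#' states of the same or greater severity than their origin state.
#'
#' @param origin Alive origin state, integer 0-5.
#' @return Length-7 probability vector with weight `1/(6 - origin)` on
#'   states `origin..5` and zero elsewhere.
#' @export
recurrence_redistribution <- function(origin) {
  if (origin < 0 || origin > 5)
    stop("origin must be an alive state in 0..5")
  out <- numeric(7)
  out[(origin + 1L):6L] <- 1 / (6 - origin)
  out
}

## Per-cycle building blocks shared by the transition matrix and the
## cohort accrual decomposition.
.cycle_components <- function(age, params) {
  cpy <- 1 / params$cycle_length
  p_rec <- annual_rate_to_cycle_prob(params$annual_recurrence, cpy)
  p_ns <- vapply(0:5, function(s)
    nonstroke_death_cycle_prob(age, s, params$mortality, params$hr, cpy),
    numeric(1))
  list(p_rec = p_rec, p_ns = p_ns,
       case_fatality = params$recurrence_case_fatality)
}

#' Build the per-cycle 7x7 transition matrix
#'
#' One clinical event per cycle: from each alive state `j`, a recurrence
#' occurs with the per-cycle recurrence probability; recurrence decedents
#' (per-event case fatality) move to death, survivors are redistributed
#' uniformly over states `j..5`; the non-recurring fraction dies of
#' non-stroke causes with the HR-adjusted background probability or stays
#' in `j`.  Death (mRS 6) is absorbing and no improvement transitions
#' exist.
#'
#' @param age Cohort age in years at cycle start.
#' @param params A `cea_params` object.
#' @return A 7x7 row-stochastic matrix (rows = origin mRS 0-6, columns =
#'   destination), with attribute `age`.
#' @export
build_transition_matrix <- function(age, params) {
  cc <- .cycle_components(age, params)
  P <- matrix(0, 7, 7, dimnames = list(paste0("mrs", 0:6), paste0("mrs", 0:6)))
  for (j in 0:5) {
    row <- cc$p_rec * (1 - cc$case_fatality) * recurrence_redistribution(j)
    row[j + 1L] <- row[j + 1L] + (1 - cc$p_rec) * (1 - cc$p_ns[j + 1L])
    row[7L] <- cc$p_rec * cc$case_fatality +
      (1 - cc$p_rec) * cc$p_ns[j + 1L]
    P[j + 1L, ] <- row
  }
  P[7L, 7L] <- 1
  attr(P, "age") <- age
  P
}

#' Export per-cycle transition matrices in tidy long format
#'
#' @param params A `cea_params` object.
#' @param path Optional CSV path.
#' @return A data.frame (cycle, age, from_state, to_state, probability)
#'   covering Markov cycles 1..n.
#' @export
export_transition_matrices <- function(params, path = NULL) {
  n_cycles <- as.integer(round(params$horizon_years / params$cycle_length)) - 1L
  rows <- vector("list", n_cycles)
  for (t in seq_len(n_cycles)) {
    age <- params$start_age + t * params$cycle_length
    P <- build_transition_matrix(age, params)
    rows[[t]] <- data.frame(cycle = t, age = age,
                            from_state = rep(0:6, times = 7),
                            to_state = rep(0:6, each = 7),
                            probability = as.vector(P))
  }
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
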