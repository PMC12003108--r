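#' Apply per-category risk ratios to an mRS distribution
#'
#' The treated arm's 3-month mRS distribution is the component-wise product
#' of the control distribution and the published risk ratios, renormalized
#' to sum to one (the raw product sums to ~1.0006 with the printed values;
#' the excess is CI rounding noise).  The renormalization constant is
#' recorded in attribute `renormalizer`.
#'
#' @param control Length-7 control-arm mRS probability vector.
#' @param rr Length-7 risk-ratio vector.
#' @return Length-7 probability vector summing to one, with attribute
#'   `renormalizer` = the sum of the raw products.
#' @export
apply_rr <- function(control, rr) {
  raw <- control * rr
  s <- sum(raw)
  if (s <= 0) stop("apply_rr: risk-ratio-weighted distribution is all zero")
  structure(raw / s, renormalizer = s)
}

#' Cost of a full argatroban course including infusion fees
#'
#' Dosing: continuous infusion, 60 mg/day for 2 days then 20 mg/day for 5
#' days = 220 mg total.  Administration: 7 days x 24 h continuous infusion
#' = 168 h, billed as one first-hour fee plus 167 additional-hour fees.
#'
#' @param price_per_mg Drug price in CNY per mg.
#' @param costs Cost list from a `cea_params` (uses `infusion_first_hour`
#'   and `infusion_additional_hour`).
#' @return Total course cost in CNY, with attributes `drug` (220 x price)
#'   and `infusion`.
#' @export
drug_course_cost <- function(price_per_mg, costs) {
  if (price_per_mg <= 0) stop("drug price must be positive")
  dose_mg <- 60 * 2 + 20 * 5
  infusion_hours <- 7 * 24
  drug <- dose_mg * price_per_mg
  infusion <- costs$infusion_first_hour +
    (infusion_hours - 1) * costs$infusion_additional_hour
  structure(drug + infusion, drug = drug, infusion = infusion)
}

#' Run the 3-month decision-tree stage for one arm
#'
#' Produces the initial Markov distribution (the 3-month mRS distribution:
#' the control distribution itself, or the risk-ratio-weighted distribution
#' for the argatroban arm) and the arm's acute-phase cost, QALY and
#' life-year contributions.  Acute cost sums state-mass-weighted acute-care
#' costs (mRS 0-1, mRS 2-5, death), the arm's expected sICH cost, and, in
#' the argatroban arm, the drug course.  Acute QALYs are one quarter-year
#' of the 3-month distribution's expected utility minus the expected sICH
#' disutility for one cycle; acute life years are a quarter-year of the
#' surviving mass.  Quantities occur in year 0 and are undiscounted.
#'
#' @param arm `"argatroban"` or `"control"`.
#' @param params A `cea_params` object.
#' @return An object of class `acute_phase`: list with `arm`, `dist`
#'   (initial Markov distribution), `acute_cost`, `acute_qaly`, `acute_ly`.
#' @export
run_decision_tree <- function(arm = c("argatroban", "control"), params) {
  arm <- match.arg(arm)
  cyc <- params$cycle_length
  dist <- if (arm == "argatroban") {
    d <- apply_rr(unname(params$mrs_control), unname(params$rr))
    attr(d, "renormalizer") <- NULL
    d
  } else unname(params$mrs_control)

  p_sich <- if (arm == "argatroban") params$p_sich_argatroban
            else params$p_sich_control
  co <- params$costs
  cost <- sum(dist[1:2]) * co$acute_mrs01 +
    sum(dist[3:6]) * co$acute_mrs25 +
    dist[7] * co$acute_death +
    p_sich * co$sich_cost
  if (arm == "argatroban")
    cost <- cost + as.numeric(drug_course_cost(co$drug_price_per_mg, co))

  qaly <- cyc * sum(dist * params$utilities) -
    p_sich * params$sich_disutility * cyc
  ly <- cyc * (1 - dist[7])

  structure(list(arm = arm, dist = dist, acute_cost = cost,
                 acute_qaly = qaly, acute_ly = ly),
            class = "acute_phase")
}

#' @export
print.acute_phase <- function(x, ...) {
  cat(sprintf("Acute phase (%s): cost %.1f CNY, QALY %.4f, LY %.4f\n",
              x$arm, x$acute_cost, x$acute_qaly, x$acute_ly))
  cat("  3-month mRS distribution:",
      paste(sprintf("%.4f", x$dist), collapse = " "), "\n")
  invisible(x)
}
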