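#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes incremental discounted cost, QALYs and life years, the ICER
#' (CNY per QALY and per LY), net monetary benefit at both willingness-
#' to-pay thresholds, and the threshold classification: cheaper and more
#' effective is *dominant*; costlier and less effective is *dominated*;
#' otherwise an ICER below the 1x-GDP threshold is *highly cost-effective*,
#' between 1x and 3x GDP *cost-effective*, and above 3x GDP
#' *not cost-effective*.  Full-precision totals are classified; printed
#' tables round for presentation only.
#'
#' @param intervention,comparator `arm_result` objects computed under the
#'   same parameter set and horizon.
#' @param wtp_1x,wtp_3x Willingness-to-pay thresholds in CNY per QALY
#'   (defaults: 2023 Chinese per-capita GDP and three times it).
#' @return An object of class `cea_result`.
#' @export
compute_icer <- function(intervention, comparator,
                         wtp_1x = 89358, wtp_3x = 268074) {
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qaly - comparator$total_qaly
  dly <- intervention$total_ly - comparator$total_ly
  icer <- if (de != 0) dc / de else NA_real_
  icer_ly <- if (dly != 0) dc / dly else NA_real_

  classification <-
    if (dc < 0 && de > 0) "dominant"
    else if (dc > 0 && de < 0) "dominated"
    else if (de == 0) { if (dc > 0) "dominated" else "dominant" }
    else if (icer < wtp_1x) "highly cost-effective"
    else if (icer <= wtp_3x) "cost-effective"
    else "not cost-effective"

  structure(list(
    intervention = list(arm = intervention$arm,
                        cost = intervention$total_cost,
                        qaly = intervention$total_qaly,
                        ly = intervention$total_ly),
    comparator = list(arm = comparator$arm,
                      cost = comparator$total_cost,
                      qaly = comparator$total_qaly,
                      ly = comparator$total_ly),
    delta_cost = dc, delta_qaly = de, delta_ly = dly,
    icer = icer, icer_ly = icer_ly,
    classification = classification,
    wtp_1x = wtp_1x, wtp_3x = wtp_3x,
    nmb_1x = de * wtp_1x - dc, nmb_3x = de * wtp_3x - dc
  ), class = "cea_result")
}

#' Run the full two-arm cost-effectiveness model
#'
#' The package's central entry point: runs the 3-month decision tree and
#' the quarterly Markov cohort model for both arms under one parameter
#' set and compares them.
#'
#' @param params A `cea_params` object (default: the published base case).
#' @return An object of class `cea`: list with `argatroban` and `control`
#'   (`arm_result`s), `result` (a `cea_result`), and `params`.
#' @examples
#' fit <- run_cea(default_parameters())
#' print(fit)
#' @export
run_cea <- function(params = default_parameters()) {
  arm_arg <- run_markov(run_decision_tree("argatroban", params), params)
  arm_ctl <- run_markov(run_decision_tree("control", params), params)
  structure(list(
    argatroban = arm_arg,
    control = arm_ctl,
    result = compute_icer(arm_arg, arm_ctl, params$wtp_1x, params$wtp_3x),
    params = params
  ), class = "cea")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("  %-12s cost %10.0f CNY   %6.3f QALY   %6.3f LY\n",
              x$comparator$arm, x$comparator$cost, x$comparator$qaly,
              x$comparator$ly))
  cat(sprintf("  %-12s cost %10.0f CNY   %6.3f QALY   %6.3f LY\n",
              x$intervention$arm, x$intervention$cost, x$intervention$qaly,
              x$intervention$ly))
  cat(sprintf("  incremental: %0.0f CNY, %0.3f QALY, %0.3f LY\n",
              x$delta_cost, x$delta_qaly, x$delta_ly))
  cat(sprintf("  ICER: %0.0f CNY/QALY (%0.0f CNY/LY) -> %s\n",
              x$icer, x$icer_ly, x$classification))
  invisible(x)
}

#' @export
print.cea <- function(x, ...) {
  cat("Decision-tree + Markov cost-effectiveness analysis\n")
  print(x$result)
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  r <- object$result
  out <- data.frame(
    arm = c(r$comparator$arm, r$intervention$arm),
    total_cost = c(r$comparator$cost, r$intervention$cost),
    total_qaly = c(r$comparator$qaly, r$intervention$qaly),
    total_ly = c(r$comparator$ly, r$intervention$ly),
    delta_cost = c(NA, r$delta_cost),
    delta_qaly = c(NA, r$delta_qaly),
    delta_ly = c(NA, r$delta_ly),
    icer = c(NA, r$icer))
  attr(out, "classification") <- r$classification
  out
}

#' Serialize a CEA result as a flat record
#'
#' @param cea A `cea` or `cea_result` object.
#' @param path Optional JSON path.
#' @return Named list mirroring the published result-table columns.
#' @export
export_cea_result <- function(cea, path = NULL) {
  r <- if (inherits(cea, "cea")) cea$result else cea
  rec <- list(
    comparator_cost = r$comparator$cost, comparator_qaly = r$comparator$qaly,
    comparator_ly = r$comparator$ly,
    intervention_cost = r$intervention$cost,
    intervention_qaly = r$intervention$qaly,
    intervention_ly = r$intervention$ly,
    delta_cost = r$delta_cost, delta_qaly = r$delta_qaly,
    delta_ly = r$delta_ly, icer = r$icer, icer_ly = r$icer_ly,
    classification = r$classification)
  if (!is.null(path))
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  rec
}
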