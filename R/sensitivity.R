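#' One-way (tornado) sensitivity analysis
#'
#' Each scalar parameter carrying a published range is pushed to its low
#' and high bound in turn, all other inputs held at their point values,
#' and the full two-arm model is re-run deterministically.  Bars are
#' ranked by `|ICER(high) - ICER(low)|`.  A `sign_crossing` flag marks
#' parameters whose extreme flips the sign of incremental cost or
#' effectiveness (dominance or effectiveness loss at an extreme).  mRS
#' distribution categories are not varied one-way (a single-category move
#' breaks the composition; their uncertainty enters the PSA Dirichlet).
#'
#' @param params A `cea_params` object.
#' @param parameters Optional character vector restricting which
#'   parameters are varied (default: all ranged scalars).
#' @return An object of classes `cea_tornado`/`data.frame` with columns
#'   parameter, low, high, icer_low, icer_high, width, the incremental
#'   QALYs, LYs and costs at each extreme, a `less_effective` flag
#'   (incremental QALYs or LYs negative at an extreme) and a
#'   `sign_crossing` flag (incremental cost or effectiveness changes sign
#'   at an extreme, so the ICER there is negative); sorted by descending
#'   width.
#' @export
one_way_sensitivity <- function(params, parameters = NULL) {
  rng <- params$ranges
  rng <- rng[rng$family != "dirichlet" & rng$high > rng$low, , drop = FALSE]
  if (!is.null(parameters))
    rng <- rng[rng$parameter %in% parameters, , drop = FALSE]
  base <- run_cea(params)$result

  one <- function(nm, value) {
    run_cea(set_param(params, nm, value))$result
  }
  rows <- lapply(seq_len(nrow(rng)), function(i) {
    nm <- rng$parameter[i]
    lo <- one(nm, rng$low[i]); hi <- one(nm, rng$high[i])
    data.frame(parameter = nm, low = rng$low[i], high = rng$high[i],
               icer_low = lo$icer, icer_high = hi$icer,
               width = abs(hi$icer - lo$icer),
               delta_e_low = lo$delta_qaly, delta_e_high = hi$delta_qaly,
               delta_ly_low = lo$delta_ly, delta_ly_high = hi$delta_ly,
               delta_c_low = lo$delta_cost, delta_c_high = hi$delta_cost,
               less_effective = (lo$delta_qaly < 0 | hi$delta_qaly < 0 |
                                   lo$delta_ly < 0 | hi$delta_ly < 0),
               sign_crossing = (sign(lo$delta_qaly) != sign(base$delta_qaly) |
                                  sign(hi$delta_qaly) != sign(base$delta_qaly) |
                                  sign(lo$delta_cost) != sign(base$delta_cost) |
                                  sign(hi$delta_cost) != sign(base$delta_cost)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer
  class(out) <- c("cea_tornado", "data.frame")
  out
}

#' @export
print.cea_tornado <- function(x, n = 10, ...) {
  cat(sprintf("One-way sensitivity analysis: %d parameters, base ICER %.0f\n",
              nrow(x), attr(x, "base_icer")))
  print.data.frame(utils::head(
    x[, c("parameter", "low", "high", "icer_low", "icer_high", "width",
          "sign_crossing")], n), digits = 5)
  invisible(x)
}

#' @param x A `cea_tornado`.
#' @param n Number of top bars to draw.
#' @param ... Passed to [graphics::barplot()].
#' @rdname one_way_sensitivity
#' @export
plot.cea_tornado <- function(x, n = 15, ...) {
  d <- utils::head(x, n)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_icer")
  lo <- pmin(d$icer_low, d$icer_high) - base
  hi <- pmax(d$icer_low, d$icer_high) - base
  graphics::par(mar = c(4, 12, 2, 1))
  ylim <- c(0, nrow(d) + 1)
  graphics::plot(NULL, xlim = range(c(lo, hi, 0)), ylim = ylim,
                 yaxt = "n", xlab = "ICER - base ICER (CNY/QALY)",
                 ylab = "", main = "Tornado diagram", ...)
  for (i in seq_len(nrow(d)))
    graphics::rect(lo[i], i - 0.35, hi[i], i + 0.35, col = "steelblue")
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Export tornado results
#' @param tornado A `cea_tornado`.
#' @param path Optional CSV path.
#' @return The underlying data.frame.
#' @export
export_tornado <- function(tornado, path = NULL) {
  out <- as.data.frame(tornado)
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}

#' Deterministic scenario analysis
#'
#' Re-runs the full model with named overrides applied to the base
#' parameter set.  Overrides may address any canonical scalar parameter
#' (see [set_param()]) plus `start_age`, `horizon_years` and
#' `mortality_table` (a replacement mortality data.frame, required for
#' cohorts starting below the default table's first band).
#'
#' @param params A `cea_params` object.
#' @param overrides Named list of overrides.
#' @return A `cea` object.
#' @examples
#' run_scenario(default_parameters(),
#'              list(drug_price_per_mg = 25.5))
#' @export
run_scenario <- function(params, overrides = list()) {
  for (nm in names(overrides)) {
    if (nm == "mortality_table") {
      params$mortality <- overrides[[nm]]
    } else {
      params <- set_param(params, nm, overrides[[nm]])
      i <- match(nm, params$ranges$parameter)
      if (!is.na(i)) {  # widen the stored range to bracket the override
        params$ranges$low[i] <- min(params$ranges$low[i], overrides[[nm]])
        params$ranges$high[i] <- max(params$ranges$high[i], overrides[[nm]])
      }
    }
  }
  validate_parameters(params)
  run_cea(params)
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter sets: costs from moment-matched gamma
#' distributions, scalar probabilities and utilities from betas, risk and
#' hazard ratios from median-preserving lognormals, and the control mRS
#' distribution from a Dirichlet ([fit_psa_distributions()]).  Each draw is
#' run through the full two-arm model, giving incremental cost and QALY
#' pairs, the cost-effectiveness acceptability curve over a WTP grid
#' (0 to 300,000 CNY in 1,000-CNY steps), the fraction of draws with
#' positive net monetary benefit at the 1x-GDP threshold ("highly
#' cost-effective"), and the fraction dominant.  Draws are independent;
#' a master seed spawns one sub-seed per draw, so results are reproducible
#' and order-independent.  Structurally invalid draws (a sampled
#' probability outside \[0,1\]) are rejected and redrawn, with a count kept.
#'
#' @param params A `cea_params` object.
#' @param n Number of Monte-Carlo draws (default 10,000).
#' @param seed Master seed.
#' @param wtp_grid WTP grid for the CEAC.
#' @return An object of class `cea_psa`: `draws` data.frame
#'   (draw, delta_cost, delta_qaly), `ceac` data.frame (wtp, probability),
#'   `fraction_highly_ce`, `fraction_dominant`, `n`, `seed`, `n_rejected`,
#'   and the deterministic `base` `cea_result`.
#' @export
run_psa <- function(params, n = 10000, seed = 1,
                    wtp_grid = seq(0, 300000, by = 1000)) {
  stopifnot(n >= 1)
  fits <- fit_psa_distributions(params)
  base <- run_cea(params)$result

  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)

  scalar_names <- setdiff(names(fits), "mrs_distribution")
  dc <- de <- numeric(n)
  n_rejected <- 0L

  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    repeat {
      p_i <- params
      p_i$mrs_control[] <- as.vector(draw_fitted(fits$mrs_distribution, 1))
      ok <- TRUE
      for (nm in scalar_names) {
        v <- draw_fitted(fits[[nm]], 1)
        if ((nm %in% c(.prob_fields, paste0("u", 0:5), "u_recurrence",
                       "sich_disutility")) && (v < 0 || v > 1)) {
          ok <- FALSE; break
        }
        p_i <- set_param(p_i, nm, v)
      }
      if (ok) break
      n_rejected <- n_rejected + 1L
    }
    r <- run_cea(p_i)$result
    dc[i] <- r$delta_cost; de[i] <- r$delta_qaly
  }

  nmb1 <- de * params$wtp_1x - dc
  ceac <- data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(w) mean(de * w - dc > 0),
                         numeric(1)))

  structure(list(
    draws = data.frame(draw = seq_len(n), delta_cost = dc, delta_qaly = de),
    ceac = ceac,
    fraction_highly_ce = mean(nmb1 > 0),
    fraction_dominant = mean(dc < 0 & de > 0),
    n = n, seed = seed, n_rejected = n_rejected,
    wtp_1x = params$wtp_1x, base = base
  ), class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d draws (seed %d)\n",
              x$n, x$seed))
  cat(sprintf("  mean incremental cost %.0f CNY, mean incremental QALY %.3f\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qaly)))
  cat(sprintf("  highly cost-effective at WTP %s: %.2f%%; dominant: %.2f%%\n",
              format(x$wtp_1x, big.mark = ","),
              100 * x$fraction_highly_ce, 100 * x$fraction_dominant))
  if (x$n_rejected > 0)
    cat(sprintf("  (%d invalid draws rejected and redrawn)\n", x$n_rejected))
  invisible(x)
}

#' @param x A `cea_psa`.
#' @param what `"plane"` for the cost-effectiveness plane scatter,
#'   `"ceac"` for the acceptability curve.
#' @param ... Passed to the underlying plot call.
#' @rdname run_psa
#' @export
plot.cea_psa <- function(x, what = c("plane", "ceac"), ...) {
  what <- match.arg(what)
  if (what == "plane") {
    graphics::plot(x$draws$delta_qaly, x$draws$delta_cost, pch = 16,
                   cex = 0.3, col = grDevices::adjustcolor("steelblue", 0.4),
                   xlab = "Incremental effectiveness (QALY)",
                   ylab = "Incremental cost (CNY)",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(0, x$wtp_1x, lty = 2)
    graphics::abline(h = 0, v = 0, col = "grey")
  } else {
    graphics::plot(x$ceac$wtp, x$ceac$probability, type = "l",
                   xlab = "Willingness to pay (CNY/QALY)",
                   ylab = "P(positive net monetary benefit)",
                   ylim = c(0, 1),
                   main = "Cost-effectiveness acceptability curve", ...)
    graphics::abline(v = x$wtp_1x, lty = 2)
  }
  invisible(x)
}

#' Export PSA draws or the CEAC
#' @param psa A `cea_psa`.
#' @param path Optional CSV path.
#' @return The draws data.frame.
#' @export
export_psa <- function(psa, path = NULL) {
  if (!is.null(path))
    utils::write.csv(psa$draws, path, row.names = FALSE, quote = FALSE)
  psa$draws
}

#' @rdname export_psa
#' @export
export_ceac <- function(psa, path = NULL) {
  if (!is.null(path))
    utils::write.csv(psa$ceac, path, row.names = FALSE, quote = FALSE)
  psa$ceac
}
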