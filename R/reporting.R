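#' Render base-case and scenario results as a publication-style table
#'
#' Two rows per analysis block (control then argatroban) with columns
#' total cost, total effectiveness (QALY, LY), incremental cost,
#' incremental effectiveness (QALY, LY) and ICER.  Costs and ICERs are
#' rounded to whole CNY with thousands separators, QALYs and LYs to two
#' decimals.  Rendering is deterministic: identical inputs give a
#' byte-identical file.
#'
#' @param base A `cea` object for the base case.
#' @param scenarios Named list of `cea` objects (may be empty).
#' @param path Optional output path for the plain-text table.
#' @return Character vector of table lines, invisibly when written.
#' @export
render_table2 <- function(base, scenarios = list(), path = NULL) {
  fmtc <- function(x) formatC(round(x), format = "d", big.mark = ",")
  fmt2 <- function(x) formatC(x, format = "f", digits = 2)
  row <- function(label, cells)
    paste(c(formatC(label, width = 12, flag = "-"),
            formatC(cells, width = 12)), collapse = " ")
  block <- function(label, fit) {
    r <- fit$result
    c(label,
      row(r$comparator$arm,
          c(fmtc(r$comparator$cost), fmt2(r$comparator$qaly),
            fmt2(r$comparator$ly), "", "", "", "")),
      row(r$intervention$arm,
          c(fmtc(r$intervention$cost), fmt2(r$intervention$qaly),
            fmt2(r$intervention$ly), fmtc(r$delta_cost),
            fmt2(r$delta_qaly), fmt2(r$delta_ly), fmtc(r$icer))))
  }
  header <- row("", c("Cost(CNY)", "QALY", "LY", "dCost", "dQALY", "dLY",
                      "ICER"))
  lines <- c(header, block("Base case", base))
  for (nm in names(scenarios))
    lines <- c(lines, block(nm, scenarios[[nm]]))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Write a run manifest
#'
#' Records a digest of the parameter values, the seed(s), package version,
#' subcommand and output files of a run.  The digest is the MD5 of the
#' canonical YAML serialization of the parameter set, so it changes iff
#' any input value changes.
#'
#' @param params The `cea_params` used.
#' @param path JSON output path.
#' @param subcommand Label of the analysis run.
#' @param seed Seed(s) used, if any.
#' @param outputs Character vector of files written.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(params, path, subcommand = "base",
                               seed = NULL, outputs = character()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_parameters(params, tmp)
  manifest <- list(
    config_digest = unname(tools::md5sum(tmp)),
    seed = seed,
    package_version = as.character(utils::packageVersion("strokeCEA")),
    subcommand = subcommand,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' Export a per-arm acute/total summary record
#'
#' @param cea A `cea` object.
#' @param path Optional CSV path.
#' @return Data.frame with one row per arm: acute cost/QALY/LY, totals,
#'   and the initial Markov distribution `p0..p6`.
#' @export
export_arm_summary <- function(cea, path = NULL) {
  row <- function(ar) {
    d <- as.list(stats::setNames(ar$acute$dist, paste0("p", 0:6)))
    data.frame(arm = ar$arm, acute_cost = ar$acute$acute_cost,
               acute_qaly = ar$acute$acute_qaly, acute_ly = ar$acute$acute_ly,
               total_cost = ar$total_cost, total_qaly = ar$total_qaly,
               total_ly = ar$total_ly, d)
  }
  out <- rbind(row(cea$control), row(cea$argatroban))
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}

#' Command-line entry point
#'
#' Thin driver over the package's functions, used by the
#' `inst/cli/stroke_cea.R` script.  Subcommands: `base`, `owsa`,
#' `psa --n --seed`, `scenario --drug-price --start-age`, and
#' `simulate-trial --n --seed`.  Outputs (CSV/JSON and a run manifest) are
#' written to `--outdir`.
#'
#' @param args Character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly (0 on success).
#' @export
cea_cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: stroke_cea.R <subcommand> [options]",
    "subcommands:",
    "  base           [--config FILE] [--outdir DIR]",
    "  owsa           [--config FILE] [--outdir DIR]",
    "  psa            [--config FILE] [--outdir DIR] [--n N] [--seed S]",
    "  scenario       [--config FILE] [--outdir DIR] [--drug-price P]",
    "                 [--start-age A]",
    "  simulate-trial [--config FILE] [--outdir DIR] [--n N] [--seed S]",
    sep = "\n")
  if (length(args) < 1 || args[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(args) < 1) 2L else 0L))
  }
  sub <- args[1]
  if (!sub %in% c("base", "owsa", "psa", "scenario", "simulate-trial")) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(2L))
  }
  if (!requireNamespace("optparse", quietly = TRUE)) {
    message("the 'optparse' package is required for the command line")
    return(invisible(2L))
  }
  opts <- list(
    optparse::make_option("--config", type = "character",
      default = system.file("extdata", "default_ease_china.yaml",
                            package = "strokeCEA")),
    optparse::make_option("--outdir", type = "character", default = "."),
    optparse::make_option("--n", type = "integer", default = 10000L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--drug-price", type = "double", default = NA,
                          dest = "drug_price"),
    optparse::make_option("--start-age", type = "double", default = NA,
                          dest = "start_age"))
  parsed <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = opts),
                         args = args[-1]),
    error = function(e) e)
  if (inherits(parsed, "error")) {
    message("usage error: ", conditionMessage(parsed))
    return(invisible(2L))
  }

  status <- tryCatch({
    params <- load_parameters(parsed$config)
    dir.create(parsed$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(parsed$outdir, f)
    t0 <- Sys.time()
    outputs <- switch(sub,
      base = {
        fit <- run_cea(params)
        export_cea_result(fit, out("cea_result.json"))
        render_table2(fit, path = out("table2.txt"))
        export_arm_summary(fit, out("arm_summary.csv"))
        c("cea_result.json", "table2.txt", "arm_summary.csv")
      },
      owsa = {
        export_tornado(one_way_sensitivity(params), out("tornado.csv"))
        "tornado.csv"
      },
      psa = {
        psa <- run_psa(params, n = parsed$n, seed = parsed$seed)
        export_psa(psa, out("psa_draws.csv"))
        export_ceac(psa, out("ceac.csv"))
        jsonlite::write_json(
          list(n = psa$n, seed = psa$seed,
               fraction_highly_ce = psa$fraction_highly_ce,
               fraction_dominant = psa$fraction_dominant),
          out("psa_summary.json"), auto_unbox = TRUE, digits = NA)
        c("psa_draws.csv", "ceac.csv", "psa_summary.json")
      },
      scenario = {
        ov <- list()
        if (!is.na(parsed$drug_price))
          ov$drug_price_per_mg <- parsed$drug_price
        if (!is.na(parsed$start_age)) ov$start_age <- parsed$start_age
        fit <- run_scenario(params, ov)
        export_cea_result(fit, out("scenario_result.json"))
        "scenario_result.json"
      },
      `simulate-trial` = {
        trial <- simulate_trial(unname(params$mrs_control), unname(params$rr),
                                n_per_arm = parsed$n, seed = parsed$seed)
        export_trial(trial, out("trial_counts.csv"),
                     out("trial_parameters.yaml"))
        c("trial_counts.csv", "trial_parameters.yaml")
      })
    seed_used <- if (sub %in% c("psa", "simulate-trial")) parsed$seed else NULL
    write_run_manifest(params, out("manifest.json"), subcommand = sub,
                       seed = seed_used, outputs = outputs)
    message(sprintf("%s: wrote %s (%.2f s)", sub,
                    paste(outputs, collapse = ", "),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
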