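test_that("bundled default configuration loads the published inputs", {
  p <- base_params
  expect_s3_class(p, "cea_params")
  expect_equal(unname(p$mrs_control), tab_mrs)
  expect_equal(unname(p$rr), tab_rr)
  expect_equal(unname(p$hr), c(1, 1, 1.11, 1.27, 1.71, 2.37))
  expect_equal(p$costs$drug_price_per_mg, 1.614)
  expect_equal(p$costs$recurrent_stroke_cost, 18380)
  expect_equal(p$discount_rate, 0.05)
  expect_equal(p$wtp_1x, 89358)
  expect_equal(p$wtp_3x, 268074)
  expect_equal(p$horizon_years / p$cycle_length, 120)
  expect_equal(unname(p$utilities), c(0.95, 0.89, 0.67, 0.44, 0.16, 0.1, 0))
})

test_that("missing optional settings fall back to defaults; errors name keys", {
  cfg <- yaml::read_yaml(system.file("extdata", "default_ease_china.yaml",
                                     package = "strokeCEA"))
  cfg$settings$discount_rate <- NULL
  f <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(cfg), f)
  expect_equal(load_parameters(f)$discount_rate, 0.05)

  cfg2 <- cfg
  cfg2$risk_ratios <- NULL
  writeLines(yaml::as.yaml(cfg2), f)
  expect_error(load_parameters(f), "risk_ratios")

  cfg3 <- yaml::read_yaml(system.file("extdata", "default_ease_china.yaml",
                                      package = "strokeCEA"))
  cfg3$probabilities$p_sich_control$value <- 1.5
  cfg3$probabilities$p_sich_control$high <- 1.5
  writeLines(yaml::as.yaml(cfg3), f)
  expect_error(load_parameters(f), "p_sich_control")
})

test_that("save/load round trip reproduces every stored value exactly", {
  f <- tempfile(fileext = ".yaml")
  save_parameters(base_params, f)
  p2 <- load_parameters(f)
  for (nm in c("mrs_control", "rr", "hr", "utilities", "u_recurrence",
               "sich_disutility", "p_sich_argatroban", "p_sich_control",
               "annual_recurrence", "recurrence_case_fatality", "costs",
               "discount_rate", "start_age", "horizon_years",
               "cycle_length", "wtp_1x", "wtp_3x"))
    expect_identical(p2[[nm]], base_params[[nm]], label = nm)
  expect_identical(p2$mortality, base_params$mortality)
  expect_identical(p2$ranges, base_params$ranges)
})

test_that("beta moment matching recovers mean and sd from point + range", {
  fd <- fit_beta_from_summary(0.21, 0.189, 0.232)
  # oracle: nu = m(1-m)/s^2 - 1, alpha = m nu, beta = (1-m) nu
  s <- (0.232 - 0.189) / 3.92
  nu <- 0.21 * 0.79 / s^2 - 1
  expect_equal(unname(fd$par), c(0.21 * nu, 0.79 * nu), tolerance = 1e-10)
  expect_equal(unname(fd$par), c(289.325, 1088.413), tolerance = 1e-4)
  expect_equal(dist_mean(fd), 0.21, tolerance = 1e-9)
  expect_equal(dist_sd(fd), 0.01096939, tolerance = 1e-6)

  expect_equal(fit_beta_from_summary(0.5, 0.5, 0.5)$family, "point")

  fd2 <- fit_beta_from_summary(0.112, 0.096, 0.128)
  expect_equal(dist_mean(fd2), 0.112, tolerance = 1e-9)

  expect_error(fit_beta_from_summary(0.5, 0.6, 0.7))
})

test_that("gamma moment matching recovers mean and sd", {
  fd <- fit_gamma_from_summary(18380, 13785, 22976)
  expect_equal(dist_mean(fd), 18380, tolerance = 1e-6 * 18380)
  expect_equal(dist_sd(fd), 2344.643, tolerance = 1e-2)
  expect_equal(fit_gamma_from_summary(100, 100, 100)$family, "point")
})

test_that("lognormal CI fit preserves the median", {
  fd <- fit_lognormal_from_ci(1.63, 1.10, 2.40)
  expect_equal(unname(fd$par["meanlog"]), 0.48858, tolerance = 1e-4)
  expect_equal(unname(fd$par["sdlog"]), 0.199020, tolerance = 1e-5)
  expect_equal(unname(exp(fd$par["meanlog"])), 1.63, tolerance = 1e-9)
  expect_equal(fit_lognormal_from_ci(1, 1, 1)$family, "point")
  expect_error(fit_lognormal_from_ci(-1, 0.5, 2))
})

test_that("Dirichlet fit matches marginal means and implied sample size", {
  lo <- base_params$ranges$low[1:7]
  hi <- base_params$ranges$high[1:7]
  fd <- fit_dirichlet_from_ranges(tab_mrs, lo, hi)
  expect_equal(dist_mean(fd), tab_mrs, tolerance = 1e-9)
  # oracle: implied n for category 0 alone is m(1-m)/sd^2 ~ 304
  sd0 <- (hi[1] - lo[1]) / 3.92
  expect_equal(0.116 * 0.884 / sd0^2, 303.96, tolerance = 1e-2)
  expect_equal(sum(fd$par), 303.136, tolerance = 1e-2)

  # uniform composition with identical ranges -> symmetric alphas
  fd_sym <- fit_dirichlet_from_ranges(rep(1 / 4, 4), rep(0.15, 4),
                                      rep(0.35, 4))
  expect_true(max(abs(fd_sym$par - fd_sym$par[1])) < 1e-12)
})

test_that("every fitted PSA family recovers its source moments", {
  fits <- fit_psa_distributions(base_params)
  rng <- base_params$ranges
  for (i in seq_len(nrow(rng))) {
    nm <- rng$parameter[i]
    if (rng$family[i] %in% c("dirichlet", "fixed") || rng$high[i] == rng$low[i])
      next
    fd <- fits[[nm]]
    point <- strokeCEA:::.get_param(base_params, nm)
    target_sd <- (rng$high[i] - rng$low[i]) / 3.92
    if (fd$family == "lognormal") {
      expect_equal(unname(exp(fd$par["meanlog"])), point,
                   tolerance = 1e-9, label = nm)
    } else {
      expect_equal(dist_mean(fd), point, tolerance = 0.01 * point + 1e-12,
                   label = nm)
      expect_equal(dist_sd(fd), target_sd, tolerance = 0.01 * target_sd,
                   label = nm)
    }
  }
})

test_that("sample means of 50,000 draws match analytic means within 3 SE", {
  set.seed(402)
  n <- 50000
  for (fd in list(fit_beta_from_summary(0.21, 0.189, 0.232),
                  fit_gamma_from_summary(18380, 13785, 22976),
                  fit_lognormal_from_ci(1.63, 1.10, 2.40))) {
    x <- draw_fitted(fd, n)
    expect_lt(abs(mean(x) - dist_mean(fd)), 3 * dist_sd(fd) / sqrt(n))
  }
  fd <- fit_dirichlet_from_ranges(tab_mrs, base_params$ranges$low[1:7],
                                  base_params$ranges$high[1:7])
  x <- draw_fitted(fd, n)
  expect_true(all(abs(colMeans(x) - dist_mean(fd)) <
                    3 * dist_sd(fd) / sqrt(n)))
})

test_that("PSA distribution export has one row per scalar and category", {
  tab <- export_psa_distributions(base_params)
  expect_true(all(c("parameter", "family", "par1", "par2") %in% names(tab)))
  expect_equal(sum(tab$family == "dirichlet"), 7)
  expect_true("drug_price_per_mg" %in% tab$parameter)
  f <- tempfile(fileext = ".csv")
  export_psa_distributions(base_params, f)
  expect_true(file.exists(f))
})

test_that("set_param addresses every canonical name and renormalizes mRS", {
  p <- set_param(base_params, "rr6", 1.3)
  expect_equal(unname(p$rr[7]), 1.3)
  p <- set_param(base_params, "mrs0", 0.3)
  expect_equal(sum(p$mrs_control), 1, tolerance = 1e-12)
  p <- set_param(base_params, "annual_post_mrs01", 2655)
  expect_equal(p$costs$annual_post_mrs01, 2655)
  expect_error(set_param(base_params, "nonexistent", 1), "unknown parameter")
})
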