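test_that("tornado extremes equal independent single-parameter scenario runs", {
  tor <- one_way_sensitivity(base_params,
                             parameters = c("drug_price_per_mg", "rr6",
                                            "annual_post_mrs01"))
  expect_s3_class(tor, "cea_tornado")
  for (nm in tor$parameter) {
    row <- tor[tor$parameter == nm, ]
    lo <- run_scenario(base_params, stats::setNames(list(row$low), nm))
    hi <- run_scenario(base_params, stats::setNames(list(row$high), nm))
    expect_equal(row$icer_low, lo$result$icer, tolerance = 1e-12, label = nm)
    expect_equal(row$icer_high, hi$result$icer, tolerance = 1e-12, label = nm)
  }
  expect_true(all(diff(tor$width) <= 0))
})

test_that("a zero-width range produces a zero-width bar", {
  p <- base_params
  i <- match("sich_cost", p$ranges$parameter)
  p$ranges$low[i] <- p$ranges$high[i] <- p$costs$sich_cost
  tor <- one_way_sensitivity(p, parameters = c("sich_cost", "rr0"))
  expect_false("sich_cost" %in% tor$parameter)  # no width left to vary
  tor2 <- one_way_sensitivity(p, parameters = "rr0")
  expect_gt(tor2$width[1], 0)
})

test_that("rr6 at its upper bound makes argatroban less effective", {
  tor <- one_way_sensitivity(base_params, parameters = "rr6")
  # extra deaths cut incremental life years below zero and flip the sign
  # of incremental cost, so the ICER at that extreme is negative
  expect_lt(tor$delta_ly_high, 0)
  expect_lt(tor$icer_high, 0)
  expect_true(tor$less_effective)
  expect_true(tor$sign_crossing)
})

test_that("the annual mRS 0-1 cost at its low end makes argatroban dominant", {
  s <- run_scenario(base_params, list(annual_post_mrs01 = 2655))
  expect_equal(s$result$classification, "dominant")
  expect_lt(s$result$delta_cost, 0)
})

test_that("scenarios apply overrides and reduce to the base case without them", {
  base <- run_cea(base_params)
  s0 <- run_scenario(base_params, list())
  expect_equal(s0$result$icer, base$result$icer, tolerance = 1e-12)

  s <- run_scenario(base_params, list(drug_price_per_mg = 25.5))
  expect_equal(s$result$delta_cost - base$result$delta_cost,
               220 * (25.5 - 1.614), tolerance = 1e-6)
  expect_equal(s$result$delta_qaly, base$result$delta_qaly, tolerance = 1e-12)

  expect_error(run_scenario(base_params, list(start_age = 60)), "band")
  alt <- rbind(data.frame(age_low = 60, age_high = 66,
                          annual_probability = 0.008),
               base_params$mortality)
  s60 <- run_scenario(base_params, list(start_age = 60,
                                        mortality_table = alt))
  expect_true(is.finite(s60$result$icer))
})

test_that("a degenerate PSA reproduces the deterministic base case exactly", {
  p <- base_params
  vals <- strokeCEA:::.get_param_values(p, p$ranges$parameter)
  p$ranges$low <- vals
  p$ranges$high <- vals
  psa <- run_psa(p, n = 5, seed = 99)
  base <- run_cea(p)$result
  expect_equal(psa$draws$delta_cost, rep(base$delta_cost, 5),
               tolerance = 1e-9)
  expect_equal(psa$draws$delta_qaly, rep(base$delta_qaly, 5),
               tolerance = 1e-9)
  expect_equal(psa$fraction_highly_ce, 1)
})

test_that("PSA is seed-deterministic and its CEAC starts at P(cost saving)", {
  a <- run_psa(base_params, n = 40, seed = 7)
  b <- run_psa(base_params, n = 40, seed = 7)
  expect_identical(a$draws, b$draws)
  expect_identical(a$ceac, b$ceac)

  expect_equal(a$ceac$probability[a$ceac$wtp == 0],
               mean(a$draws$delta_cost < 0))
  expect_true(all(a$ceac$probability >= 0 & a$ceac$probability <= 1))
  expect_equal(a$fraction_highly_ce,
               mean(a$draws$delta_qaly * 89358 - a$draws$delta_cost > 0))
  # CE-plane fraction below the WTP line equals the NMB>0 fraction
  below <- with(a$draws, delta_cost < delta_qaly * 89358)
  expect_equal(mean(below), a$fraction_highly_ce)
})

test_that("PSA sampled parameters recover their fitted means", {
  fits <- fit_psa_distributions(base_params)
  set.seed(31)
  n <- 10000
  for (nm in c("recurrent_stroke_cost", "u3", "rr0", "annual_recurrence")) {
    fd <- fits[[nm]]
    x <- draw_fitted(fd, n)
    expect_lt(abs(mean(x) - dist_mean(fd)), 3 * dist_sd(fd) / sqrt(n))
  }
})

test_that("tornado and PSA exports round-trip through CSV", {
  tor <- one_way_sensitivity(base_params, parameters = c("rr0", "rr6"))
  f <- tempfile(fileext = ".csv")
  export_tornado(tor, f)
  expect_equal(nrow(utils::read.csv(f)), 2)

  psa <- run_psa(base_params, n = 10, seed = 1)
  f2 <- tempfile(fileext = ".csv")
  export_psa(psa, f2)
  expect_equal(nrow(utils::read.csv(f2)), 10)
  f3 <- tempfile(fileext = ".csv")
  export_ceac(psa, f3)
  expect_equal(nrow(utils::read.csv(f3)), nrow(psa$ceac))
})
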