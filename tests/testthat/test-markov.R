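test_that("discount factors match closed form", {
  expect_equal(discount_factor(1, 0.05), 0.952381, tolerance = 1e-6)
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(0, 0), 1)
  expect_equal(discount_factor(20, 0.05), 0.3768895, tolerance = 1e-6)
  expect_error(discount_factor(-1, 0.05))
})

test_that("cycle accruals follow the published per-state amounts", {
  p <- base_params
  occ <- c(0, 0, 0, 1, 0, 0, 0)
  acc <- cycle_accruals(occ, rep(0, 7), p)
  expect_equal(acc$cost, 13492 / 4)
  expect_equal(acc$qaly, 0.44 / 4)
  expect_equal(acc$ly, 0.25)

  dead <- c(0, 0, 0, 0, 0, 0, 1)
  acc0 <- cycle_accruals(dead, rep(0, 7), p)
  expect_equal(c(acc0$cost, acc0$qaly, acc0$ly), c(0, 0, 0))

  # 0.1 newly recurred, all surviving (case fatality zeroed)
  p0 <- set_param(p, "recurrence_case_fatality", 0)
  occ <- c(0, 0, 0.5, 0.5, 0, 0, 0)
  newrec <- c(0, 0, 0.1, 0, 0, 0, 0)
  acc1 <- cycle_accruals(occ, newrec, p0)
  base1 <- cycle_accruals(occ, rep(0, 7), p0)
  # redistribution keeps the mass in mRS 2-5, so only the event cost differs
  expect_equal(acc1$cost - base1$cost, 0.1 * 18380, tolerance = 1e-9)
  # recurring mass is valued at the recurrence utility instead of u2
  expect_equal(acc1$qaly - base1$qaly, 0.25 * 0.1 * (0.42 - 0.67),
               tolerance = 1e-12)
  expect_error(cycle_accruals(occ, c(0.6, rep(0, 6)), p0))
})

test_that("a cohort starting dead accrues nothing beyond the acute phase", {
  acute <- structure(list(arm = "control", dist = c(rep(0, 6), 1),
                          acute_cost = 1000, acute_qaly = 0, acute_ly = 0),
                     class = "acute_phase")
  res <- run_markov(acute, base_params)
  expect_equal(res$total_cost, 1000)
  expect_equal(res$total_qaly, 0)
  expect_equal(res$total_ly, 0)
})

test_that("an immortal full-health cohort matches the closed-form QALY sum", {
  p <- base_params
  p$annual_recurrence <- 0
  p$discount_rate <- 0
  p$mortality <- data.frame(age_low = 60, age_high = Inf,
                            annual_probability = 0)
  p$mrs_control[] <- c(1, 0, 0, 0, 0, 0, 0)
  acute <- run_decision_tree("control", p)
  res <- run_markov(acute, p)
  markov_qaly <- res$total_qaly - acute$acute_qaly
  expect_equal(markov_qaly, 0.95 * 0.25 * 119, tolerance = 1e-9)
  expect_equal(res$total_ly - acute$acute_ly, 0.25 * 119, tolerance = 1e-9)
})

test_that("mass is conserved and the dead state is absorbing", {
  res <- run_markov(run_decision_tree("argatroban", base_params), base_params)
  occ <- as.matrix(res$trace[, paste0("state", 0:6)])
  expect_equal(unname(rowSums(occ)), rep(1, nrow(occ)), tolerance = 1e-9)
  expect_true(all(diff(occ[, 7]) >= -1e-12))
  expect_equal(nrow(res$trace), 119)
})

test_that("totals are additive and discounting is a strict contraction", {
  res <- run_markov(run_decision_tree("control", base_params), base_params)
  expect_equal(res$total_cost,
               res$acute$acute_cost + sum(res$trace$cost_disc))
  expect_equal(res$total_qaly,
               res$acute$acute_qaly + sum(res$trace$qaly_disc))
  expect_lt(res$total_cost, res$undiscounted$total_cost)
  expect_lt(res$total_qaly, res$undiscounted$total_qaly)
  expect_true(all(res$trace$cost_disc <= res$trace$cost))

  # strictly decreasing total QALYs in the discount rate
  q <- vapply(c(0, 0.03, 0.05, 0.08), function(r) {
    p <- set_param(base_params, "discount_rate", r)
    run_markov(run_decision_tree("control", p), p)$total_qaly
  }, numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("truncating the horizon never increases totals", {
  acute <- run_decision_tree("control", base_params)
  full <- run_markov(acute, base_params, n_cycles = 119)
  short <- run_markov(acute, base_params, n_cycles = 60)
  expect_lt(short$total_cost, full$total_cost)
  expect_lt(short$total_qaly, full$total_qaly)
  expect_lt(short$total_ly, full$total_ly)
})

test_that("cohort totals agree with a 100,000-walker microsimulation", {
  acute <- run_decision_tree("control", base_params)
  res <- run_markov(acute, base_params)
  ms <- microsim_arm(acute$dist, base_params, n_cycles = 119,
                     n_walkers = 100000, seed = 4711)
  expect_lt(abs((res$total_cost - acute$acute_cost) - ms$mean_cost),
            3 * ms$se_cost)
  expect_lt(abs((res$total_qaly - acute$acute_qaly) - ms$mean_qaly),
            3 * ms$se_qaly)
  expect_lt(abs((res$total_ly - acute$acute_ly) - ms$mean_ly),
            3 * ms$se_ly)
})

test_that("trace export is tidy and matrix export is row-stochastic", {
  res <- run_markov(run_decision_tree("control", base_params), base_params,
                    n_cycles = 5)
  long <- export_trace(res)
  expect_equal(nrow(long), 5 * 7)
  expect_equal(sum(long$occupancy[long$cycle == 3]), 1, tolerance = 1e-9)

  tm <- export_transition_matrices(base_params)
  expect_equal(nrow(tm), 119 * 49)
  s <- tapply(tm$probability, list(tm$cycle, tm$from_state), sum)
  expect_true(all(abs(s - 1) < 1e-12))
})
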