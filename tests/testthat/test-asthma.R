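test_that("the asthma model is valid and starts at the requested medication rate", {
  b <- build_asthma_model(asthma_params())
  expect_true(validate_model(b$model, initial = b$initial)$ok)
  tr <- run_cohort(b$model, b$rewards, b$initial)
  med1 <- sum(tr$occupancy[2, paste0("med.",
                                     c("none", "exac", "er", "admit"))])
  expect_equal(med1, 0.80, tolerance = 1e-3)
  expect_equal(rowSums(tr$occupancy), rep(1, 61), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("without exacerbations or deaths attendance hits the ceiling", {
  params <- asthma_params_no_death(
    p_exac = c(med = 0, nomed = 0), p_er = c(med = 0, nomed = 0),
    p_admit = c(med = 0, nomed = 0))
  out <- run_asthma_scenario(params, 0.80, 60, "adult",
                             persistence = "base")
  expect_equal(out$attended_days, 60 * 21.67, tolerance = 1e-9)
  expect_equal(out$missed_days, 0)
  expect_equal(out$deaths, 0)
})

test_that("event-free QALY accrual is the fixed-mix identity", {
  params <- asthma_params_no_death(
    p_exac = c(med = 0, nomed = 0), p_er = c(med = 0, nomed = 0),
    p_admit = c(med = 0, nomed = 0))
  frozen <- list(med = c(none = 1, exac = 1, er = 1, admit = 1),
                 nomed = c(none = 0, exac = 0, er = 0, admit = 0))
  for (r in c(0.25, 0.80)) {
    out <- run_asthma_scenario(params, r, 60, "adult",
                               persistence = frozen)
    expect_equal(out$qalys, 60 * (r * 0.0748 + (1 - r) * 0.0756),
                 tolerance = 1e-12)
  }
})

test_that("single-month expected missed days match the hand expectation at full adherence", {
  params <- asthma_params_no_death()
  out <- suppressWarnings(
    run_asthma_scenario(params, med_use_rate = 1, horizon_months = 1,
                        population = "adult", persistence = "base"))
  expect_equal(out$missed_days, 0.27 * 3 + 0.0382 * 4 + 0.0035 * 7,
               tolerance = 1e-12)
})

test_that("scenario persistence mappings hold the cohort rate at its target", {
  params <- asthma_params()
  # printed sets for 70/80/90
  for (r in c(0.70, 0.80, 0.90)) {
    pers <- asthma_persistence(r, params)
    expect_lt(abs(stationary_med_use(params, pers) - r), 0.01)
  }
  # calibrated sets hit the target exactly
  for (r in c(0.55, 0.60, 0.65)) {
    pers <- asthma_persistence(r, params)
    expect_equal(stationary_med_use(params, pers), r,
                 tolerance = 1e-12)
  }
  expect_error(asthma_persistence(0.99, params), "calibrate")
})

test_that("under base persistence the medication-use fraction drifts gradually upward", {
  out <- run_asthma_scenario(asthma_params(), 0.80,
                             persistence = "base")
  frac <- out$med_use_fraction
  expect_gte(frac[60], frac[1])
  expect_lt(max(abs(diff(frac))), 0.01)  # gradual, not a jump
})

test_that("cumulative mortality stays below 1% for all scenario rates", {
  for (r in c(0.60, 0.70, 0.80, 0.90)) {
    out <- run_asthma_scenario(asthma_params(), r)
    expect_lt(out$deaths, 0.01)
  }
})

test_that("attendance and QALYs rise, event costs fall, with medication use", {
  sweep <- run_asthma_sweep(asthma_params())
  g <- function(o) as.numeric(sweep[sweep$output == o, -1])
  expect_true(all(diff(g("attended_days")) >= 0))
  expect_true(all(diff(g("qalys")) >= 0))
  expect_true(all(diff(g("direct_cost_events")) <= 0))
})

test_that("monthly utilities embody the 30/365-year month convention", {
  p <- asthma_params()
  ratio_med <- p$utility_month["med", "none"] /
    p$daily_utilities[["normal_med"]]
  ratio_nomed <- p$utility_month["nomed", "none"] /
    p$daily_utilities[["normal_nomed"]]
  expect_equal(ratio_med, 30 / 365, tolerance = 0.01)
  expect_equal(ratio_nomed, 30 / 365, tolerance = 0.01)
})

test_that("children accrue school days on the 15-day scale with parent day mapping", {
  adult <- run_asthma_scenario(asthma_params(), 0.80, 60, "adult")
  child <- run_asthma_scenario(asthma_params(), 0.80, 60, "child")
  expect_equal(child$attended_days + child$missed_days, 60 * 15,
               tolerance = child$deaths * 60 * 15 + 1e-9)
  # same event process, so identical missed days; parent indirect cost
  # maps one-to-one by default
  expect_equal(child$missed_days, adult$missed_days, tolerance = 1e-9)
  expect_equal(child$indirect_cost, adult$indirect_cost,
               tolerance = 1e-9)
  half <- run_asthma_scenario(
    asthma_params(parent_workday_ratio = 0.5), 0.80, 60, "child")
  expect_equal(half$indirect_cost, 0.5 * child$indirect_cost)
})

test_that("comparisons decompose the direct-cost delta and vanish for equal rates", {
  cmp0 <- compare_med_use_scenarios(low_rate = 0.80, high_rate = 0.80)
  expect_equal(cmp0$diff, rep(0, nrow(cmp0)))
  cmp <- compare_med_use_scenarios(low_rate = 0.80, high_rate = 0.90)
  d <- function(o) cmp$diff[cmp$output == o]
  expect_equal(d("direct_cost_total"),
               d("direct_cost_events") + d("direct_cost_medication"),
               tolerance = 1e-9)
  expect_lt(d("direct_cost_events"), 0)   # fewer events
  expect_gt(d("direct_cost_medication"), 0)  # more medication
})

test_that("nonstandard horizons are flagged", {
  expect_warning(run_asthma_scenario(asthma_params(),
                                     horizon_months = 18), "standard")
})

test_that("asthma cohort expectations match the micro-simulation", {
  b <- build_asthma_model(asthma_params(), horizon_months = 24)
  tr <- run_cohort(b$model, b$rewards, b$initial)
  sim <- run_microsim(b$model, b$rewards, b$initial, 20000, seed = 9)
  for (ch in c("utility", "attended_days", "cost_events",
               "cost_medication")) {
    expect_lt(abs(sim$mean[[ch]] - tr$per_person[[ch]]),
              3 * sim$se[[ch]])
  }
})
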