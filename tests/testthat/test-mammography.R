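test_that("pattern mixes reproduce the published 70% and 80% decompositions", {
  m70 <- pattern_mix_for_hedis(0.70)
  expect_equal(unname(m70$proportions),
               c(0.197, 0.395, 0.270, 0.138))
  m80 <- pattern_mix_for_hedis(0.80)
  expect_equal(unname(m80$proportions),
               c(0.242, 0.483, 0.182, 0.093))
  # HEDIS identity holds on the published 70% mix
  p <- m70$proportions
  expect_equal(p[["annual"]] + p[["biennial"]] + 0.4 * p[["sporadic"]],
               0.700, tolerance = 1e-12)
})

test_that("solved pattern mixes satisfy the constraint system", {
  for (h in c(0.40, 0.60, 0.75, 0.90, 1.0)) {
    p <- pattern_mix_for_hedis(h)$proportions
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
    expect_equal(p[["annual"]] + p[["biennial"]] + 0.4 * p[["sporadic"]],
                 h, tolerance = 1e-9)
    expect_equal(p[["biennial"]], 2 * p[["annual"]], tolerance = 1e-9)
  }
  expect_error(pattern_mix_for_hedis(0.10), "binding constraint")
  expect_error(pattern_mix_for_hedis(1.5), "\\[0, 1\\]")
})

test_that("the built model is a valid Markov chain for every variant", {
  params <- mammography_params()
  for (v in c("base", "I", "IV", "fp_cost", "fp_cost_rescreen")) {
    b <- build_mammography_model(params, 0.70, v)
    rep <- validate_model(b$model, initial = b$initial)
    expect_true(rep$ok)
    tr <- run_cohort(b$model, b$rewards, b$initial)
    expect_equal(rowSums(tr$occupancy), rep(1, 6), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("with incidence zero the model collapses to the no-cancer closed form", {
  params <- mammography_params(
    incidence_screened = c(annual = 0, biennial = 0, sporadic = 0),
    incidence_unscreened = 0)
  out <- run_mammography_scenario(params, 0.70)
  expect_equal(out$life_expectancy, sum(0.99^(1:5)), tolerance = 1e-12)
  expect_equal(out$missed_work_cost, 0)
  expect_equal(out$qalys, sum(0.99^(1:5)), tolerance = 1e-12)
  # medical cost is screening cost only
  expect_equal(out$medical_cost,
               out$mammograms * mammography_params()$cost_mammogram,
               tolerance = 1e-9)
})

test_that("worse stage at diagnosis strictly lowers life expectancy", {
  base <- run_mammography_scenario(mammography_params(), 0.70)
  all_iv <- c(InSitu = 0, I = 0, II = 0, III = 0, IV = 1)
  params_iv <- mammography_params(
    stage_dist_screened = list(annual = all_iv, biennial = all_iv,
                               sporadic = all_iv),
    stage_dist_unscreened = all_iv)
  worst <- run_mammography_scenario(params_iv, 0.70)
  expect_lt(worst$life_expectancy, base$life_expectancy)
})

test_that("replacing screened stage distributions with the unscreened one weakly reduces life expectancy", {
  params <- mammography_params()
  u <- params$stage_dist_unscreened
  no_shift <- mammography_params(
    stage_dist_screened = list(annual = u, biennial = u, sporadic = u))
  expect_lte(run_mammography_scenario(no_shift, 0.70)$life_expectancy,
             run_mammography_scenario(params, 0.70)$life_expectancy)
})

test_that("comparing a scenario with itself gives exactly zero deltas", {
  cmp <- compare_hedis_scenarios(low_rate = 0.70, high_rate = 0.70)
  expect_equal(cmp$diff, rep(0, nrow(cmp)))
})

test_that("QALY gains exceed life-expectancy gains under screening improvement", {
  cmp <- compare_hedis_scenarios(low_rate = 0.70, high_rate = 0.80)
  d <- function(o) cmp$diff[cmp$output == o]
  expect_gte(d("qalys"), d("life_expectancy"))
})

test_that("outcomes are monotone in the HEDIS screening rate", {
  rates <- c(0.60, 0.70, 0.80, 0.90)
  runs <- lapply(rates, function(h)
    run_mammography_scenario(mammography_params(), h))
  le <- vapply(runs, `[[`, numeric(1), "life_expectancy")
  qa <- vapply(runs, `[[`, numeric(1), "qalys")
  emp <- vapply(runs, `[[`, numeric(1), "employment_years")
  expect_true(all(diff(le) >= 0))
  expect_true(all(diff(qa) >= 0))
  expect_true(all(diff(emp) >= 0))
  # cancer-treatment cost (excluding screening) is non-increasing
  treat <- vapply(runs, function(r)
    r$medical_cost - r$mammograms * mammography_params()$cost_mammogram,
    numeric(1))
  expect_true(all(diff(treat) <= 0))
})

test_that("treatment-year day allocation preserves the 44.5-day cohort mean", {
  params <- mammography_params()
  days <- days_missed_by_stage(params)
  expect_true(all(diff(days) > 0))  # later stage, more days
  # reconstruct the first-cycle diagnosis mix at the 70% base mix
  mix <- pattern_mix_for_hedis(0.70)$proportions
  sigma1 <- c(annual = 1, biennial = 1, sporadic = 0.2, none = 0)
  w <- 0
  for (g in names(mix)) {
    scr <- if (g == "none") 0 else
      params$incidence_screened[[g]] * params$stage_dist_screened[[g]]
    w <- w + mix[[g]] * (sigma1[[g]] * scr + (1 - sigma1[[g]]) *
      params$incidence_unscreened * params$stage_dist_unscreened)
  }
  expect_equal(sum(days * w / sum(w)), params$days_missed_mean,
               tolerance = 1e-9)
})

test_that("cohort expectations match the micro-simulation on the screening model", {
  b <- build_mammography_model(mammography_params(), 0.70)
  tr <- run_cohort(b$model, b$rewards, b$initial)
  sim <- run_microsim(b$model, b$rewards, b$initial, 20000, seed = 5)
  for (ch in c("survival", "utility", "direct_cost", "days")) {
    expect_lt(abs(sim$mean[[ch]] - tr$per_person[[ch]]),
              3 * sim$se[[ch]])
  }
})
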