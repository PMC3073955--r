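test_that("sensitivity diff columns are recomputed, not copied", {
  sens <- run_stage_sensitivity(variants = c("base", "II"))
  expect_equal(sens$diff, sens$high - sens$low, tolerance = 1e-12)
  direct <- compare_hedis_scenarios(mammography_params(), 0.70, 0.80,
                                    variant = "base")
  le_sens <- sens[sens$variant == "base" &
                    sens$output == "life_expectancy", "diff"]
  le_direct <- direct$diff[direct$output == "life_expectancy"]
  expect_equal(le_sens, le_direct)
})

test_that("repeating a variant id yields identical columns", {
  sens <- run_stage_sensitivity(variants = c("III", "III"))
  half <- nrow(sens) / 2
  expect_equal(sens$diff[seq_len(half)], sens$diff[-seq_len(half)])
})

test_that("more optimistic stage distributions never decrease the gains", {
  sens <- run_stage_sensitivity(variants = c("I", "base", "II", "III",
                                             "IV"))
  for (o in c("life_expectancy", "qalys")) {
    d <- sens[sens$output == o, ]
    d <- d$diff[match(c("I", "base", "II", "III", "IV"), d$variant)]
    expect_true(all(diff(d) >= 0))
  }
})

test_that("with a zero false-positive rate the fp variant collapses to base", {
  params <- mammography_params(false_positive_rate = 0)
  base <- compare_hedis_scenarios(params, 0.70, 0.80, "base")
  fp <- compare_hedis_scenarios(params, 0.70, 0.80, "fp_cost")
  expect_equal(fp$diff, base$diff, tolerance = 1e-12)
  expect_equal(fp$low, base$low, tolerance = 1e-12)
})

test_that("false-positive costs shrink the screening saving", {
  base <- compare_hedis_scenarios(mammography_params(), 0.70, 0.80)
  d <- function(cmp, o) cmp$diff[cmp$output == o]
  base_total <- d(base, "medical_cost") + d(base, "missed_work_cost")
  fp <- run_false_positive_variant()
  expect_gt(fp$total_delta, base_total)  # less negative: smaller saving
  expect_lt(fp$total_delta, 0)           # but still a saving
})

test_that("the comparison table assembles rows with consistent totals", {
  mammo <- compare_hedis_scenarios(mammography_params(), 0.70, 0.80)
  a10 <- compare_med_use_scenarios(asthma_params(), 0.80, 0.90)
  a20 <- compare_med_use_scenarios(asthma_params(), 0.70, 0.90)
  tab <- build_comparison_table(mammo, a10, a20)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$total_delta,
               tab$direct_delta + tab$indirect_delta,
               tolerance = 1e-9)
  # turnover makes the mammography indirect saving larger in magnitude
  expect_lt(tab$indirect_delta[2], tab$indirect_delta[1])
  # near-linearity: the 20-point row is about twice the 10-point row
  expect_lt(abs(tab$total_delta[4] - 2 * tab$total_delta[3]),
            0.10 * abs(tab$total_delta[4]))
  expect_error(build_comparison_table(NULL, a10), "mammo_cmp")
})
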