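# Named experiments: the stage-distribution sensitivity sweep, the
# false-positive model variants, the medication-rate scenario sweep,
# and the cross-domain employer business-case comparison table.

#' Stage-distribution sensitivity analysis
#'
#' Runs the mammography model at a low and a high HEDIS rate for each
#' model variant and tabulates the five headline outputs. Variants
#' `"I"` to `"IV"` move the screened stage-at-diagnosis distributions
#' from the most pessimistic corner of the published ranges (no stage
#' benefit from mammography) to the most optimistic corner; these are
#' reconstructions anchored by the ordering of the published
#' sensitivity results. Diff columns are always recomputed, never
#' copied.
#'
#' @param params A [mammography_params()] object.
#' @param variants Character vector of variant ids.
#' @param hedis_pair Length-2 numeric, low and high HEDIS rates.
#' @param assumptions An [economic_assumptions()] object.
#' @return Data frame with columns `variant`, `output`, `low`, `high`,
#'   `diff`.
#' @export
run_stage_sensitivity <- function(params = mammography_params(),
                                  variants = c("base", "I", "II",
                                               "III", "IV"),
                                  hedis_pair = c(0.70, 0.80),
                                  assumptions = economic_assumptions()) {
  stopifnot(length(hedis_pair) == 2L, hedis_pair[1] < hedis_pair[2])
  keep <- c("life_expectancy", "qalys", "employment_years",
            "missed_work_cost", "medical_cost")
  res <- lapply(variants, function(v) {
    cmp <- compare_hedis_scenarios(params, hedis_pair[1], hedis_pair[2],
                                   variant = v,
                                   assumptions = assumptions)
    cmp <- cmp[cmp$output %in% keep, ]
    cbind(variant = v, cmp)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' False-positive variants of the mammography business case
#'
#' Re-runs the HEDIS comparison with false-positive follow-up costs
#' included (each mammogram in a cancer-free woman triggers follow-up
#' cost with probability `false_positive_rate`), optionally with the
#' rescreen behaviour in which a false positive raises subsequent
#' mammography probability by `rescreen_boost` in relative terms.
#'
#' @inheritParams run_stage_sensitivity
#' @param include_rescreen_boost Include the post-false-positive
#'   rescreen behaviour.
#' @return A [business_case_row()] (no turnover) with the per-person
#'   direct, days and indirect deltas; the full comparison data frame
#'   is attached as attribute `"comparison"`.
#' @export
run_false_positive_variant <- function(params = mammography_params(),
                                       include_rescreen_boost = FALSE,
                                       hedis_pair = c(0.70, 0.80),
                                       assumptions =
                                         economic_assumptions()) {
  variant <- if (include_rescreen_boost) "fp_cost_rescreen" else
    "fp_cost"
  cmp <- compare_hedis_scenarios(params, hedis_pair[1], hedis_pair[2],
                                 variant = variant,
                                 assumptions = assumptions)
  d <- function(o) cmp$diff[cmp$output == o]
  row <- business_case_row(
    label = sprintf("Mammography +%.0f%% (%s)",
                    100 * diff(hedis_pair), variant),
    direct_delta = d("medical_cost"),
    days_delta = d("missed_days"),
    indirect_delta = d("missed_work_cost"),
    turnover_included = FALSE
  )
  attr(row, "comparison") <- cmp
  row
}

#' Medication-rate scenario sweep for the asthma model
#'
#' @inheritParams run_asthma_scenario
#' @param rates Medication-use rates to evaluate.
#' @return Data frame with one row per output and one column per rate,
#'   mirroring the scenario-sweep report layout.
#' @export
run_asthma_sweep <- function(params = asthma_params(),
                             rates = c(0.60, 0.70, 0.80, 0.90),
                             horizon_months = 60,
                             population = c("adult", "child"),
                             assumptions = economic_assumptions()) {
  population <- match.arg(population)
  outs <- c("qalys", "attended_days", "missed_days",
            "direct_cost_events", "direct_cost_medication",
            "direct_cost_total", "indirect_cost", "deaths")
  cols <- lapply(rates, function(r) {
    sc <- run_asthma_scenario(params, r, horizon_months, population,
                              assumptions = assumptions)
    vapply(outs, function(o) sc[[o]], numeric(1))
  })
  out <- data.frame(output = outs, do.call(cbind, cols),
                    stringsAsFactors = FALSE)
  names(out)[-1L] <- sprintf("rate_%.0f", 100 * rates)
  rownames(out) <- NULL
  out
}

#' Assemble the employer business-case comparison table
#'
#' Combines the mammography HEDIS comparison with the adult asthma
#' 10- and 20-point comparisons into one table of per-person deltas
#' (direct medical cost, days off work, indirect cost, total). The
#' mammography intervention appears twice: absenteeism-only indirect
#' cost, and absenteeism plus turnover.
#'
#' @param mammo_cmp Result of [compare_hedis_scenarios()].
#' @param asthma_cmp_10 Result of [compare_med_use_scenarios()] for a
#'   10-point rate increase (adults).
#' @param asthma_cmp_20 Result for a 20-point increase, or `NULL` to
#'   omit the row.
#' @param assumptions An [economic_assumptions()] object.
#' @return Object of class `comparison_report`: a data frame of
#'   [business_case_row()]s with metadata attributes.
#' @export
build_comparison_table <- function(mammo_cmp, asthma_cmp_10,
                                   asthma_cmp_20 = NULL,
                                   assumptions = economic_assumptions()) {
  for (nm in c("mammo_cmp", "asthma_cmp_10")) {
    x <- get(nm)
    if (!is.data.frame(x) || !all(c("output", "diff") %in% names(x))) {
      stop("missing or malformed input row: ", nm)
    }
  }
  dm <- function(cmp, o) cmp$diff[cmp$output == o]
  rows <- list(
    business_case_row(
      "Mammography rate +10% (no turnover)",
      direct_delta = dm(mammo_cmp, "medical_cost"),
      days_delta = dm(mammo_cmp, "missed_days"),
      indirect_delta = dm(mammo_cmp, "missed_work_cost"),
      turnover_included = FALSE),
    business_case_row(
      "Mammography rate +10% (with turnover)",
      direct_delta = dm(mammo_cmp, "medical_cost"),
      days_delta = dm(mammo_cmp, "missed_days"),
      indirect_delta = dm(mammo_cmp, "missed_work_cost") +
        dm(mammo_cmp, "turnover_cost"),
      turnover_included = TRUE),
    business_case_row(
      "Asthma medication use +10% (adults)",
      direct_delta = dm(asthma_cmp_10, "direct_cost_total"),
      days_delta = -dm(asthma_cmp_10, "attended_days"),
      indirect_delta = dm(asthma_cmp_10, "indirect_cost"),
      turnover_included = FALSE)
  )
  if (!is.null(asthma_cmp_20)) {
    rows <- c(rows, list(business_case_row(
      "Asthma medication use +20% (adults)",
      direct_delta = dm(asthma_cmp_20, "direct_cost_total"),
      days_delta = -dm(asthma_cmp_20, "attended_days"),
      indirect_delta = dm(asthma_cmp_20, "indirect_cost"),
      turnover_included = FALSE)))
  }
  out <- do.call(rbind, rows)
  attr(out, "assumptions") <- assumptions
  class(out) <- c("comparison_report", class(out))
  out
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> per-person deltas",
      "(savings negative)\n")
  y <- as.data.frame(x)
  for (col in c("direct_delta", "indirect_delta", "total_delta")) {
    y[[col]] <- sprintf("$%.2f", y[[col]])
  }
  y$days_delta <- sprintf("%.2f", y$days_delta)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a scenario table to CSV
#'
#' @param x A data frame (sensitivity table, sweep, or comparison
#'   report).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
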