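# Employer-facing economics: wages, absenteeism, turnover, and the
# business-case table assembled from per-person model deltas.

#' Economic assumptions for the employer perspective
#'
#' @param hourly_wage Average hourly wage (USD/hour; Department of Labor
#'   May 2007 average, 21.31).
#' @param hours_per_day Hours worked per day (8).
#' @param hours_per_year Full-time hours per year (2080).
#' @param turnover_fraction Cost of replacing an employee as a fraction
#'   of the new hire's annual salary (0.33).
#' @param currency_rounding Decimal places used when *printing* money in
#'   reports; full precision is always retained internally.
#' @return Object of class `economic_assumptions`.
#' @export
economic_assumptions <- function(hourly_wage = 21.31, hours_per_day = 8,
                                 hours_per_year = 2080,
                                 turnover_fraction = 0.33,
                                 currency_rounding = 2) {
  if (hourly_wage <= 0 || hours_per_day <= 0 || hours_per_year <= 0) {
    stop("wage and hours must be positive")
  }
  if (turnover_fraction < 0 || turnover_fraction > 1) {
    stop("turnover_fraction must lie in [0, 1]")
  }
  structure(
    list(hourly_wage = hourly_wage, hours_per_day = hours_per_day,
         hours_per_year = hours_per_year,
         turnover_fraction = turnover_fraction,
         currency_rounding = currency_rounding),
    class = "economic_assumptions"
  )
}

#' Cost of absenteeism to the employer
#'
#' Lost productivity is hours lost times the hourly wage: `days *
#' hours_per_day * hourly_wage`. Linear in both days and wage.
#'
#' @param days Work-days missed (>= 0).
#' @param assumptions An [economic_assumptions()] object.
#' @return Cost in currency units (full precision, not rounded).
#' @examples
#' absenteeism_cost(5.08)  # 866.04: five-year saving per adult with asthma
#' @export
absenteeism_cost <- function(days, assumptions = economic_assumptions()) {
  if (any(days < 0)) stop("days must be >= 0")
  days * assumptions$hours_per_day * assumptions$hourly_wage
}

#' Annual cost of replacing one employee
#'
#' `turnover_fraction * hourly_wage * hours_per_year`, rounded to whole
#' currency for reporting (0.33 * 21.31 * 2080 = 14627).
#'
#' @param assumptions An [economic_assumptions()] object.
#' @return Turnover cost per workforce exit, whole currency units.
#' @export
annual_turnover_cost <- function(assumptions = economic_assumptions()) {
  round(assumptions$turnover_fraction * assumptions$hourly_wage *
          assumptions$hours_per_year)
}

#' One row of the employer business-case table
#'
#' Sign convention: deltas are (improved scenario - baseline), so
#' savings are negative, as printed in business-case reports. Totals are
#' additive: `row(a) + row(b)` component-wise equals `row(a + b)`.
#'
#' @param label Row label.
#' @param direct_delta Change in direct medical cost per person.
#' @param days_delta Change in days off work per person.
#' @param indirect_delta Change in indirect (absenteeism, optionally
#'   turnover) cost per person.
#' @param turnover_included Flag recording whether `indirect_delta`
#'   contains turnover cost.
#' @return A one-row data frame of class `business_case_row` with
#'   `total_delta = direct_delta + indirect_delta`.
#' @export
business_case_row <- function(label, direct_delta, days_delta,
                              indirect_delta, turnover_included = FALSE) {
  structure(
    data.frame(label = label,
               direct_delta = direct_delta,
               days_delta = days_delta,
               indirect_delta = indirect_delta,
               total_delta = direct_delta + indirect_delta,
               turnover_included = turnover_included,
               stringsAsFactors = FALSE),
    class = c("business_case_row", "data.frame")
  )
}

#' Scale a per-person delta to a population
#'
#' @param per_person_delta Per-person quantity (QALYs, dollars, ...).
#' @param n Population count (>= 0).
#' @param rounding Report rounding: `"none"`, `"integer"`, or
#'   `"nearest_50"` (round to the nearest 50 units, as used for
#'   headline dollar projections). Rounding is applied to the scaled
#'   result only and never feeds back into computation.
#' @return The population-scale quantity.
#' @examples
#' scale_to_population(0.00238, 10000, "integer")  # 24 QALYs
#' @export
scale_to_population <- function(per_person_delta, n,
                                rounding = c("none", "integer",
                                             "nearest_50")) {
  rounding <- match.arg(rounding)
  if (n < 0) stop("population count must be >= 0")
  x <- per_person_delta * n
  switch(rounding,
         none = x,
         integer = round(x),
         nearest_50 = 50 * round(x / 50))
}
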