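# Monthly-cycle Markov model of appropriate asthma controller-
# medication use. States are (medication status this month, event
# category this month): no exacerbation, exacerbation managed with an
# office visit, an ER/urgent-care visit, or a hospital admission, plus
# death. Event probabilities within a month depend only on current
# medication status; next-month medication status follows a
# persistence mapping indexed by this month's event.

ASTHMA_EVENTS <- c("none", "exac", "er", "admit")
ASTHMA_MED <- c("med", "nomed")
ASTHMA_HORIZONS <- c(12L, 24L, 36L, 48L, 60L)

# persistence sets printed alongside the base parameters, constrained
# so the cohort medication-use fraction stays at the scenario rate
ASTHMA_PERSISTENCE_PRESETS <- list(
  "0.7" = list(med = c(none = 0.95, exac = 0.97, er = 0.99,
                       admit = 0.99),
               nomed = c(none = 0.01, exac = 0.15, er = 0.25,
                         admit = 0.25)),
  "0.8" = list(med = c(none = 0.96, exac = 0.96, er = 0.99,
                       admit = 0.99),
               nomed = c(none = 0.01, exac = 0.25, er = 0.30,
                         admit = 0.30)),
  "0.9" = list(med = c(none = 0.965, exac = 0.99, er = 0.99,
                       admit = 0.99),
               nomed = c(none = 0.01, exac = 0.40, er = 0.45,
                         admit = 0.45))
)

#' Parameters of the asthma medication model
#'
#' Monthly event probabilities with and without appropriate controller
#' medication, the medication-persistence mapping, monthly state
#' utilities, days missed per event category, event and medication
#' costs, and the adult/child day scales. Defaults are the base-case
#' values: exacerbation rates follow the published halving of event
#' rates under inhaled corticosteroids, ER/admission rates are adjusted
#' for the higher rates observed in African-American patients, and
#' utilities derive from per-day utilities (0.92 normal day without
#' medication, 0.91 with, 0.72 exacerbation day, extra decrements 0.05
#' ER / 0.10 hospital) times days per month.
#'
#' @param med_use_rate Baseline probability of appropriate medication
#'   use (0.80; scenarios span 0.60-0.90).
#' @param p_exac Monthly probability of an exacerbation not requiring
#'   an ER visit or admission, by medication status.
#' @param p_er Monthly probability of an exacerbation with an ER or
#'   urgent-care visit, no admission.
#' @param p_admit Monthly probability of an exacerbation with hospital
#'   admission.
#' @param persistence List with elements `med` and `nomed`, each a
#'   probability of using medication *next* month indexed by this
#'   month's event category (`none`, `exac`, `er`, `admit`).
#' @param p_death_er,p_death_admit Probability of asthma death in a
#'   month with an ER visit (0.0002) or admission (0.0014); deaths
#'   occur only from these branches.
#' @param p_death_other Monthly probability of death from other causes
#'   (0.0001), applied to all live states.
#' @param utility_month Matrix `[med status, event]` of monthly QALY
#'   accruals (e.g. 0.0748 for a no-exacerbation month on medication).
#' @param daily_utilities Reference per-day utilities the monthly
#'   values derive from; metadata only, dynamics use `utility_month`.
#' @param days_available Days per month available for work (adult:
#'   2080 h / 260 d per year = 21.67) or school (child: 180 school
#'   days / 12 = 15, smoothed over the calendar year).
#' @param days_missed Days of work or school missed per month by event
#'   category (0 / 3 / 4 / 7).
#' @param cost_event Direct medical cost per event category (USD 0 /
#'   155.44 office visit / 1080 ER / 13512 admission).
#' @param cost_medication_month Monthly controller-medication cost
#'   (USD 112), charged in every month spent in a medication-using
#'   state.
#' @param parent_workday_ratio Parent work-days lost per child
#'   school-day lost (1.0).
#' @param death_cycle_fraction Fraction of the pre-death monthly
#'   utility accrued in the month of death (0.5: half a month at the
#'   pre-death utility, zero for the remainder).
#' @return Object of class `asthma_params`.
#' @export
asthma_params <- function(
    med_use_rate = 0.80,
    p_exac = c(med = 0.27, nomed = 0.53),
    p_er = c(med = 0.0382, nomed = 0.0756),
    p_admit = c(med = 0.0035, nomed = 0.0069),
    persistence = ASTHMA_PERSISTENCE_PRESETS[["0.8"]],
    p_death_er = 0.0002,
    p_death_admit = 0.0014,
    p_death_other = 0.0001,
    utility_month = rbind(
      med = c(none = 0.0748, exac = 0.0706, er = 0.0698,
              admit = 0.0649),
      nomed = c(none = 0.0756, exac = 0.0712, er = 0.0704,
                admit = 0.0654)),
    daily_utilities = c(normal_nomed = 0.92, normal_med = 0.91,
                        exac_day = 0.72, er_extra = 0.05,
                        admit_extra = 0.10, med_disutility = 0.01),
    days_available = c(adult = 21.67, child = 15),
    days_missed = c(none = 0, exac = 3, er = 4, admit = 7),
    cost_event = c(none = 0, exac = 155.44, er = 1080, admit = 13512),
    cost_medication_month = 112,
    parent_workday_ratio = 1.0,
    death_cycle_fraction = 0.5) {

  med_use_rate <- check_prob(med_use_rate, "med_use_rate")
  p_exac <- check_prob(p_exac[ASTHMA_MED], "p_exac")
  p_er <- check_prob(p_er[ASTHMA_MED], "p_er")
  p_admit <- check_prob(p_admit[ASTHMA_MED], "p_admit")
  if (any(p_exac + p_er + p_admit > 1)) {
    stop("event-category probabilities exceed 1 for one medication ",
         "status")
  }
  if (!is.list(persistence) ||
      !all(ASTHMA_MED %in% names(persistence))) {
    stop("persistence needs elements 'med' and 'nomed'")
  }
  persistence <- lapply(persistence[ASTHMA_MED], function(p)
    check_prob(p[ASTHMA_EVENTS], "persistence"))
  check_prob(c(p_death_er, p_death_admit, p_death_other), "death rates")
  utility_month <- as.matrix(utility_month)[ASTHMA_MED, ASTHMA_EVENTS]
  if (any(utility_month <= 0) || any(utility_month > 0.085)) {
    stop("utility_month values must lie in (0, 0.085]")
  }
  days_available <- days_available[c("adult", "child")]
  days_missed <- days_missed[ASTHMA_EVENTS]
  if (any(days_missed < 0) ||
      any(max(days_missed) > days_available)) {
    stop("days_missed must be >= 0 and <= days_available for each ",
         "population")
  }
  cost_event <- cost_event[ASTHMA_EVENTS]
  if (any(cost_event < 0) || cost_medication_month < 0) {
    stop("costs must be >= 0")
  }

  structure(
    list(med_use_rate = med_use_rate, p_exac = p_exac, p_er = p_er,
         p_admit = p_admit, persistence = persistence,
         p_death_er = p_death_er, p_death_admit = p_death_admit,
         p_death_other = p_death_other, utility_month = utility_month,
         daily_utilities = daily_utilities,
         days_available = days_available, days_missed = days_missed,
         cost_event = cost_event,
         cost_medication_month = cost_medication_month,
         parent_workday_ratio = parent_workday_ratio,
         death_cycle_fraction = death_cycle_fraction),
    class = "asthma_params"
  )
}

event_probs <- function(params, med) {
  p <- c(exac = params$p_exac[[med]], er = params$p_er[[med]],
         admit = params$p_admit[[med]])
  c(none = 1 - sum(p), p)[ASTHMA_EVENTS]
}

#' Cohort medication-use fraction fixed point of a persistence mapping
#'
#' @param params An [asthma_params()] object.
#' @param persistence A persistence mapping (default: the one in
#'   `params`).
#' @return The stationary fraction of the cohort using medication.
#' @export
stationary_med_use <- function(params,
                               persistence = params$persistence) {
  stay <- sum(event_probs(params, "med") * persistence$med[ASTHMA_EVENTS])
  start <- sum(event_probs(params, "nomed") *
                 persistence$nomed[ASTHMA_EVENTS])
  start / (start + 1 - stay)
}

#' Persistence mapping for a target medication-use rate
#'
#' Scenario rates are modelled with the cohort medication-use fraction
#' held at the scenario rate, mirroring the published constraint that
#' overall medication use stay constant over the simulation. Rates
#' 0.70, 0.80 and 0.90 use the printed persistence sets; other rates
#' are calibrated by scaling the off-medication restart probabilities
#' after an event (exacerbation/ER/admission) by a common factor so the
#' stationary medication-use fraction equals the target, keeping the
#' on-medication probabilities and the no-event restart at their base
#' values.
#'
#' @param rate Target medication-use rate in `[0, 1]`.
#' @param params An [asthma_params()] object supplying the base
#'   persistence and event probabilities.
#' @return A persistence list (`med`, `nomed`).
#' @export
asthma_persistence <- function(rate, params = asthma_params()) {
  rate <- check_prob(rate, "rate")
  key <- names(ASTHMA_PERSISTENCE_PRESETS)[
    match(TRUE, abs(rate - as.numeric(
      names(ASTHMA_PERSISTENCE_PRESETS))) < 1e-9)]
  if (!is.na(key)) return(ASTHMA_PERSISTENCE_PRESETS[[key]])

  base <- ASTHMA_PERSISTENCE_PRESETS[["0.8"]]
  stay <- sum(event_probs(params, "med") * base$med[ASTHMA_EVENTS])
  ev <- event_probs(params, "nomed")
  g_none <- ev[["none"]] * base$nomed[["none"]]
  g_events <- sum(ev[c("exac", "er", "admit")] *
                    base$nomed[c("exac", "er", "admit")])
  g_target <- rate * (1 - stay) / (1 - rate)
  f <- (g_target - g_none) / g_events
  restarts <- base$nomed[c("exac", "er", "admit")] * f
  if (f < 0 || any(restarts > 1)) {
    stop("cannot calibrate persistence to medication-use rate ", rate,
         ": required restart probabilities fall outside [0, 1]")
  }
  list(med = base$med,
       nomed = c(none = base$nomed[["none"]], restarts))
}

#' Build the asthma medication transition model and rewards
#'
#' Assembles the monthly-cycle [transition_model()] and
#' [reward_schedule()]. The live states are (medication status, event
#' category this month); a `Start` state distributes the cohort in
#' month 1 at the initial medication-use rate. Asthma deaths occur only
#' from months with an ER visit or admission; a small other-cause
#' hazard applies to all live states.
#'
#' @param params An [asthma_params()] object.
#' @param population `"adult"` (work days, 21.67/month) or `"child"`
#'   (school days, 15/month; parent work-days lost at
#'   `parent_workday_ratio`).
#' @param horizon_months Number of monthly cycles.
#' @param persistence Persistence mapping to use (default: the one in
#'   `params`).
#' @param initial_rate Month-1 medication-use rate (default
#'   `params$med_use_rate`).
#' @return List with `model`, `rewards`, `initial` and `meta`.
#' @export
build_asthma_model <- function(params = asthma_params(),
                               population = c("adult", "child"),
                               horizon_months = 60,
                               persistence = params$persistence,
                               initial_rate = params$med_use_rate) {
  stopifnot(inherits(params, "asthma_params"))
  population <- match.arg(population)
  horizon_months <- as.integer(horizon_months)
  if (horizon_months < 1L) stop("horizon_months must be >= 1")
  initial_rate <- check_prob(initial_rate, "initial_rate")

  live <- as.vector(outer(ASTHMA_MED, ASTHMA_EVENTS, paste, sep = "."))
  states <- c("Start", live, "Dead")
  channels <- c("survival", "utility", "attended_days", "missed_days",
                "cost_events", "cost_medication", "med_use")
  avail <- params$days_available[[population]]
  p_death_event <- c(none = 0, exac = 0, er = params$p_death_er,
                     admit = params$p_death_admit)

  # probability of landing in each (m', e') / Dead from a given
  # next-month medication probability
  land <- function(p_med) {
    out <- stats::setNames(numeric(length(states)), states)
    for (m2 in ASTHMA_MED) {
      pm <- if (m2 == "med") p_med else 1 - p_med
      if (pm == 0) next
      ev <- event_probs(params, m2)
      for (e2 in ASTHMA_EVENTS) {
        surv <- 1 - p_death_event[[e2]] - params$p_death_other
        out[paste0(m2, ".", e2)] <- pm * ev[[e2]] * surv
      }
    }
    out["Dead"] <- 1 - sum(out)
    out
  }

  P <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  P["Dead", "Dead"] <- 1
  P["Start", ] <- land(initial_rate)
  for (m in ASTHMA_MED) {
    for (e in ASTHMA_EVENTS) {
      P[paste0(m, ".", e), ] <- land(persistence[[m]][[e]])
    }
  }

  R <- matrix(0, length(states), length(channels),
              dimnames = list(states, channels))
  for (m in ASTHMA_MED) {
    for (e in ASTHMA_EVENTS) {
      s <- paste0(m, ".", e)
      R[s, "survival"] <- 1
      R[s, "utility"] <- params$utility_month[m, e]
      R[s, "attended_days"] <- avail - params$days_missed[[e]]
      R[s, "missed_days"] <- params$days_missed[[e]]
      R[s, "cost_events"] <- params$cost_event[[e]]
      R[s, "cost_medication"] <-
        if (m == "med") params$cost_medication_month else 0
      R[s, "med_use"] <- as.numeric(m == "med")
    }
  }

  model <- transition_model(states, P, n_cycles = horizon_months,
                            absorbing = "Dead", cycle_length = "month")
  rewards <- reward_schedule(R, NULL, death_states = "Dead",
                             death_cycle_fraction =
                               params$death_cycle_fraction,
                             death_credit_channels = "utility")
  initial <- stats::setNames(numeric(length(states)), states)
  initial["Start"] <- 1
  list(model = model, rewards = rewards, initial = initial,
       meta = list(population = population, avail = avail,
                   persistence = persistence,
                   initial_rate = initial_rate))
}

#' Run one asthma medication-use scenario
#'
#' @inheritParams build_asthma_model
#' @param med_use_rate Scenario medication-use rate; sets the month-1
#'   occupancy and (with `persistence = "auto"`) the persistence
#'   calibration.
#' @param persistence `"auto"` (printed sets for 0.70/0.80/0.90,
#'   calibrated otherwise, so the cohort rate stays at the scenario
#'   rate), `"base"` (base persistence regardless of rate; the cohort
#'   rate then drifts toward its fixed point, which is reported rather
#'   than suppressed), or an explicit persistence list.
#' @param assumptions An [economic_assumptions()] for indirect costs.
#' @return Object of class `asthma_outputs`: per-person expectations
#'   `qalys`, `attended_days`, `missed_days`, `direct_cost_events`,
#'   `direct_cost_medication`, `direct_cost_total`, `indirect_cost`,
#'   `deaths`, and the medication-use trajectory; `cohort_trace` as
#'   attribute `"trace"`.
#' @export
run_asthma_scenario <- function(params = asthma_params(),
                                med_use_rate = params$med_use_rate,
                                horizon_months = 60,
                                population = c("adult", "child"),
                                persistence = "auto",
                                assumptions = economic_assumptions()) {
  population <- match.arg(population)
  horizon_months <- as.integer(horizon_months)
  if (!horizon_months %in% ASTHMA_HORIZONS) {
    warning("horizon_months = ", horizon_months,
            " is outside the standard set (12, 24, 36, 48, 60)")
  }
  pers <- if (is.list(persistence)) {
    persistence
  } else if (identical(persistence, "base")) {
    params$persistence
  } else if (identical(persistence, "auto")) {
    asthma_persistence(med_use_rate, params)
  } else {
    stop("persistence must be 'auto', 'base', or a persistence list")
  }
  built <- build_asthma_model(params, population, horizon_months,
                              persistence = pers,
                              initial_rate = med_use_rate)
  trace <- run_cohort(built$model, built$rewards, built$initial)
  pp <- trace$per_person
  med_traj <- trace$occupancy[-1L,
    paste0("med.", ASTHMA_EVENTS), drop = FALSE]
  med_frac <- rowSums(med_traj)
  day_ratio <- if (population == "child")
    params$parent_workday_ratio else 1
  out <- list(
    qalys = pp[["utility"]],
    attended_days = pp[["attended_days"]],
    missed_days = pp[["missed_days"]],
    direct_cost_events = pp[["cost_events"]],
    direct_cost_medication = pp[["cost_medication"]],
    direct_cost_total = pp[["cost_events"]] + pp[["cost_medication"]],
    indirect_cost = absenteeism_cost(day_ratio * pp[["missed_days"]],
                                     assumptions),
    deaths = trace$occupancy[horizon_months + 1L, "Dead"],
    med_use_months = pp[["med_use"]],
    med_use_fraction = med_frac,
    med_use_rate = med_use_rate,
    horizon_months = horizon_months,
    population = population
  )
  attr(out, "trace") <- trace
  class(out) <- "asthma_outputs"
  out
}

#' @export
print.asthma_outputs <- function(x, ...) {
  cat(sprintf(
    "<asthma_outputs> %s, %d months, medication-use rate %.0f%%\n",
    x$population, x$horizon_months, 100 * x$med_use_rate))
  cat(sprintf("  cumulative QALYs:      %.5f\n", x$qalys))
  cat(sprintf("  attended days:         %.2f\n", x$attended_days))
  cat(sprintf("  missed days:           %.2f\n", x$missed_days))
  cat(sprintf("  event cost:            $%.2f\n", x$direct_cost_events))
  cat(sprintf("  medication cost:       $%.2f\n",
              x$direct_cost_medication))
  cat(sprintf("  cumulative deaths:     %.5f\n", x$deaths))
  invisible(x)
}

#' Compare two asthma medication-use scenarios
#'
#' Per-person deltas (high-rate scenario minus low-rate scenario;
#' savings negative) over the horizon, with the direct-cost delta
#' decomposed into event-cost savings and added medication cost.
#'
#' @inheritParams run_asthma_scenario
#' @param low_rate,high_rate Medication-use rates to compare.
#' @return Data frame with one row per output and columns `low`,
#'   `high`, `diff`.
#' @export
compare_med_use_scenarios <- function(params = asthma_params(),
                                      low_rate = 0.80,
                                      high_rate = 0.90,
                                      horizon_months = 60,
                                      population = c("adult", "child"),
                                      assumptions =
                                        economic_assumptions(),
                                      persistence = "auto") {
  if (low_rate > high_rate) stop("low_rate must be <= high_rate")
  population <- match.arg(population)
  lo <- run_asthma_scenario(params, low_rate, horizon_months,
                            population, persistence, assumptions)
  hi <- run_asthma_scenario(params, high_rate, horizon_months,
                            population, persistence, assumptions)
  outs <- c("qalys", "attended_days", "missed_days",
            "direct_cost_events", "direct_cost_medication",
            "direct_cost_total", "indirect_cost", "deaths")
  data.frame(
    output = outs,
    low = vapply(outs, function(o) lo[[o]], numeric(1)),
    high = vapply(outs, function(o) hi[[o]], numeric(1)),
    diff = vapply(outs, function(o) hi[[o]] - lo[[o]], numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
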