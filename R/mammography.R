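# Five-year annual-cycle Markov model of breast-cancer screening in a
# cohort of employed women aged 50-65, under configurable HEDIS
# two-year mammography rates. Screening acts through a stage shift:
# mammogram-detected cancers have an earlier stage-at-diagnosis
# distribution, hence higher remission probabilities, lower treatment
# cost, and better employment outcomes.

MAMMO_STAGES <- c("InSitu", "I", "II", "III", "IV")
MAMMO_INVASIVE <- c("I", "II", "III", "IV")
MAMMO_PATTERNS <- c("annual", "biennial", "sporadic", "none")
MAMMO_VARIANTS <- c("base", "I", "II", "III", "IV",
                    "fp_cost", "fp_cost_rescreen")

# corners of the published stage-at-diagnosis sensitivity ranges; both
# sum to exactly 1. The pessimistic corner equals the unscreened
# distribution (mammography confers no stage benefit at all).
MAMMO_STAGE_PESSIMISTIC <- c(InSitu = 0.04, I = 0.32, II = 0.43,
                             III = 0.13, IV = 0.08)
MAMMO_STAGE_OPTIMISTIC <- c(InSitu = 0.21, I = 0.57, II = 0.16,
                            III = 0.04, IV = 0.02)

norm_dist <- function(x, what, names = NULL) {
  if (!is.null(names)) {
    if (is.null(names(x))) names(x) <- names else x <- x[names]
  }
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(what, ": entries must be probabilities in [0, 1]")
  }
  s <- sum(x)
  if (abs(s - 1) > 1e-6) {
    stop(what, ": probabilities sum to ", format(s),
         ", not 1 (tolerance 1e-6)")
  }
  x / s
}

check_prob <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]")
  }
  x
}

#' Parameters of the mammography screening model
#'
#' Every input of the five-year screening model: annual cancer-detection
#' probabilities, stage-at-diagnosis distributions with and without a
#' mammogram, remission/recurrence/death branch probabilities, state
#' utilities and treatment disutilities, employment probabilities, and
#' unit costs. Defaults are the base-case values assembled from SEER
#' incidence data, published stage distributions for African-American
#' women (Jacobellis-Cutter for annual/biennial screens, Yood for
#' sporadic screens, Bibb for clinically detected cancers), stage-wise
#' survival calibrations, labor-force studies, and 2007 federal cost
#' data.
#'
#' @param annual_incidence Reference annual incidence in a regularly
#'   screened population (3 cancers per 1,000 mammograms in second
#'   screening rounds).
#' @param incidence_screened Probability of a cancer found in a year
#'   *with* a mammogram, by screening pattern (`annual`, `biennial`,
#'   `sporadic`). The sporadic rate is higher because of the longer
#'   interval since the last screen.
#' @param incidence_unscreened Probability of a cancer detected
#'   clinically in any year *without* a mammogram, for every pattern
#'   (8 per 1,000).
#' @param stage_dist_screened Named list of stage-at-diagnosis
#'   distributions over `InSitu, I, II, III, IV` for mammogram-detected
#'   cancers, one per screened pattern.
#' @param stage_dist_unscreened Stage distribution for clinically
#'   detected cancers.
#' @param p_remission_dx_year Probability of remission (vs progressive
#'   disease) after initial treatment, by stage at diagnosis.
#' @param p_continued_remission Probability of continued remission (vs
#'   recurrence) in each later year, by stage; printed equal to the
#'   diagnosis-year values but kept separate so either can be varied.
#' @param p_death_progression Probability of death in a year of
#'   recurrent or progressive disease (0.79).
#' @param p_death_other Annual probability of death from causes other
#'   than cancer (0.01), applied to every live state.
#' @param annual_cancer_death_rate Reported annual death rates by stage
#'   that the branch probabilities were calibrated to reproduce
#'   5/6-year survival against. Reference metadata only: dynamics use
#'   the branch probabilities.
#' @param utility_well Utility of the well, cancer-free state (1.0).
#' @param utility_remission Utility of the remission state by stage at
#'   diagnosis, also the end-of-year utility of the diagnosis year.
#' @param disutility_treatment Transition disutility subtracted during
#'   the year of active initial treatment, by stage (0 for in-situ).
#' @param utility_progressive Utility of progressive disease (0.40).
#' @param emp_well,emp_treatment,emp_remission,emp_progressive
#'   Employment probabilities: 1 when well (cohort assumed employed at
#'   entry), by stage in the treatment year and remission years, and in
#'   progressive disease.
#' @param cost_treatment Initial treatment cost by stage at diagnosis
#'   (USD). In-situ treatment cost is not published; default 0.
#' @param cost_recurrent Annual cost of treating recurrent or
#'   progressive disease (USD 33,000), also charged in the year of a
#'   recurrence and the year of a cancer death.
#' @param cost_mammogram Cost per mammogram (USD 81.86).
#' @param cost_false_positive Follow-up cost after a false-positive
#'   mammogram (USD 533; false-positive variants only).
#' @param false_positive_rate Probability a cancer-free mammogram is
#'   read as suspicious (0.10).
#' @param rescreen_boost Relative increase in subsequent mammography
#'   probability after a false positive (0.10; rescreen variant only).
#' @param days_missed_mean Mean work-days missed in the treatment year
#'   across newly diagnosed women (44.5).
#' @param days_multiplier Relative severity multipliers allocating the
#'   mean missed days across stages; rescaled internally so the
#'   diagnosis-mix-weighted mean equals `days_missed_mean` (see
#'   [days_missed_by_stage()]).
#' @param days_missed_progressive Work-days missed per year of
#'   progressive disease; `NULL` means the stage-IV treatment-year
#'   value.
#' @param horizon_years Number of annual cycles (5).
#' @param death_cycle_fraction Fraction of the diagnosis-year utility
#'   accrued by women dying within a cycle (0.5).
#' @param discount_rate Per-cycle discount rate (0: no discounting).
#' @return Object of class `mammography_params`.
#' @export
mammography_params <- function(
    annual_incidence = 0.003,
    incidence_screened = c(annual = 0.003, biennial = 0.003,
                           sporadic = 0.005),
    incidence_unscreened = 0.008,
    stage_dist_screened = list(
      annual = c(InSitu = 0.13, I = 0.41, II = 0.37, III = 0.07,
                 IV = 0.02),
      biennial = c(InSitu = 0.13, I = 0.41, II = 0.37, III = 0.07,
                   IV = 0.02),
      sporadic = c(InSitu = 0.17, I = 0.29, II = 0.40, III = 0.09,
                   IV = 0.05)
    ),
    stage_dist_unscreened = c(InSitu = 0.04, I = 0.32, II = 0.43,
                              III = 0.13, IV = 0.08),
    p_remission_dx_year = c(I = 0.975, II = 0.94, III = 0.81,
                            IV = 0.66),
    p_continued_remission = c(I = 0.975, II = 0.94, III = 0.81,
                              IV = 0.66),
    p_death_progression = 0.79,
    p_death_other = 0.01,
    annual_cancer_death_rate = c(I = 0.0075, II = 0.03, III = 0.126,
                                 IV = 0.264),
    utility_well = 1.0,
    utility_remission = c(I = 0.90, II = 0.85, III = 0.81, IV = 0.81),
    disutility_treatment = c(InSitu = 0, I = -0.10, II = -0.20,
                             III = -0.25, IV = -0.25),
    utility_progressive = 0.40,
    emp_well = 1.0,
    emp_treatment = c(InSitu = 0.86, I = 0.70, II = 0.60, III = 0.50,
                      IV = 0.40),
    emp_remission = c(I = 0.94, II = 0.88, III = 0.81, IV = 0.75),
    emp_progressive = 0.56,
    cost_treatment = c(InSitu = 0, I = 22488, II = 27213, III = 29220,
                       IV = 31476),
    cost_recurrent = 33000,
    cost_mammogram = 81.86,
    cost_false_positive = 533,
    false_positive_rate = 0.10,
    rescreen_boost = 0.10,
    days_missed_mean = 44.5,
    days_multiplier = c(InSitu = 0.25, I = 0.70, II = 1.00, III = 1.30,
                        IV = 1.60),
    days_missed_progressive = NULL,
    horizon_years = 5,
    death_cycle_fraction = 0.5,
    discount_rate = 0) {

  incidence_screened <- check_prob(
    incidence_screened[c("annual", "biennial", "sporadic")],
    "incidence_screened")
  incidence_unscreened <- check_prob(incidence_unscreened,
                                     "incidence_unscreened")
  if (!all(c("annual", "biennial", "sporadic") %in%
             names(stage_dist_screened))) {
    stop("stage_dist_screened needs annual, biennial and sporadic ",
         "distributions")
  }
  stage_dist_screened <- lapply(
    stats::setNames(nm = c("annual", "biennial", "sporadic")),
    function(g) norm_dist(stage_dist_screened[[g]],
                          paste0("stage_dist_screened$", g),
                          MAMMO_STAGES))
  stage_dist_unscreened <- norm_dist(stage_dist_unscreened,
                                     "stage_dist_unscreened",
                                     MAMMO_STAGES)
  p_remission_dx_year <- check_prob(
    p_remission_dx_year[MAMMO_INVASIVE], "p_remission_dx_year")
  p_continued_remission <- check_prob(
    p_continued_remission[MAMMO_INVASIVE], "p_continued_remission")
  p_death_progression <- check_prob(p_death_progression,
                                    "p_death_progression")
  p_death_other <- check_prob(p_death_other, "p_death_other")
  for (u in list(utility_well, utility_remission, utility_progressive)) {
    if (any(u < 0 | u > 1)) stop("utilities must lie in [0, 1]")
  }
  if (any(disutility_treatment > 0) || any(disutility_treatment < -1)) {
    stop("disutility_treatment entries must lie in [-1, 0]")
  }
  emp_treatment <- check_prob(emp_treatment[MAMMO_STAGES],
                              "emp_treatment")
  emp_remission <- check_prob(emp_remission[MAMMO_INVASIVE],
                              "emp_remission")
  emp_progressive <- check_prob(emp_progressive, "emp_progressive")
  costs <- c(cost_treatment, cost_recurrent, cost_mammogram,
             cost_false_positive)
  if (any(costs < 0)) stop("costs must be >= 0")
  false_positive_rate <- check_prob(false_positive_rate,
                                    "false_positive_rate")
  if (days_missed_mean < 0) stop("days_missed_mean must be >= 0")
  if (any(days_multiplier < 0)) stop("days_multiplier must be >= 0")
  horizon_years <- as.integer(horizon_years)
  if (horizon_years < 1L) stop("horizon_years must be >= 1")

  structure(
    list(annual_incidence = annual_incidence,
         incidence_screened = incidence_screened,
         incidence_unscreened = incidence_unscreened,
         stage_dist_screened = stage_dist_screened,
         stage_dist_unscreened = stage_dist_unscreened,
         p_remission_dx_year = p_remission_dx_year,
         p_continued_remission = p_continued_remission,
         p_death_progression = p_death_progression,
         p_death_other = p_death_other,
         annual_cancer_death_rate = annual_cancer_death_rate,
         utility_well = utility_well,
         utility_remission = utility_remission[MAMMO_INVASIVE],
         disutility_treatment = disutility_treatment[MAMMO_STAGES],
         utility_progressive = utility_progressive,
         emp_well = emp_well,
         emp_treatment = emp_treatment,
         emp_remission = emp_remission,
         emp_progressive = emp_progressive,
         cost_treatment = cost_treatment[MAMMO_STAGES],
         cost_recurrent = cost_recurrent,
         cost_mammogram = cost_mammogram,
         cost_false_positive = cost_false_positive,
         false_positive_rate = false_positive_rate,
         rescreen_boost = rescreen_boost,
         days_missed_mean = days_missed_mean,
         days_multiplier = days_multiplier[MAMMO_STAGES],
         days_missed_progressive = days_missed_progressive,
         horizon_years = horizon_years,
         death_cycle_fraction = death_cycle_fraction,
         discount_rate = discount_rate),
    class = "mammography_params"
  )
}

#' Screening-pattern mix for a HEDIS two-year mammography rate
#'
#' Decomposes a HEDIS rate (share of women with at least one mammogram
#' in two years) into the proportions following annual, biennial,
#' sporadic (one mammogram in five years) and no screening. A sporadic
#' screener falls inside the two-year HEDIS window with probability
#' 2/5, so the mix satisfies
#' `annual + biennial + 0.4 * sporadic = hedis_rate`.
#'
#' For rates 0.70 and 0.80 the published mixes are returned verbatim.
#' Other rates solve the constraint system: proportions sum to 1,
#' biennial = 2 x annual (Blanchard's 2:1 biennial-to-annual finding),
#' the HEDIS identity above, and the sporadic:none ratio fixed at
#' 0.270:0.138.
#'
#' @param hedis_rate Two-year mammography rate in `[0, 1]`.
#' @return Object of class `screening_pattern_mix`: `hedis_rate` plus
#'   `proportions` over the four patterns.
#' @examples
#' pattern_mix_for_hedis(0.70)$proportions  # .197 .395 .270 .138
#' @export
pattern_mix_for_hedis <- function(hedis_rate) {
  if (hedis_rate < 0 || hedis_rate > 1) {
    stop("hedis_rate must lie in [0, 1]")
  }
  published <- list(
    "0.7" = c(annual = 0.197, biennial = 0.395, sporadic = 0.270,
              none = 0.138),
    "0.8" = c(annual = 0.242, biennial = 0.483, sporadic = 0.182,
              none = 0.093)
  )
  key <- c("0.7", "0.8")[match(TRUE, abs(hedis_rate - c(0.7, 0.8)) < 1e-9)]
  if (!is.na(key)) {
    prop <- published[[key]]
  } else {
    rho <- 0.138 / 0.270             # none-to-sporadic ratio
    s <- (1 - hedis_rate) / (1 + rho - 0.4)
    a <- (1 - (1 + rho) * s) / 3
    if (a < -1e-12) {
      stop("no feasible nonnegative pattern mix for hedis_rate = ",
           hedis_rate, ": binding constraint annual >= 0 ",
           "(rate too low for the fixed sporadic:none ratio)")
    }
    a <- max(a, 0)
    prop <- c(annual = a, biennial = 2 * a, sporadic = s, none = rho * s)
  }
  if (abs(sum(prop) - 1) > 1e-9) {
    stop("pattern proportions do not sum to 1")
  }
  implied <- prop[["annual"]] + prop[["biennial"]] +
    0.4 * prop[["sporadic"]]
  # the published 80% mix satisfies the identity only to 2.2e-3, so the
  # check is looser than the solver's own precision
  if (abs(implied - hedis_rate) > 5e-3) {
    stop(sprintf(
      "pattern mix implies HEDIS rate %.4f, requested %.4f", implied,
      hedis_rate))
  }
  structure(list(hedis_rate = hedis_rate, proportions = prop),
            class = "screening_pattern_mix")
}

#' @export
print.screening_pattern_mix <- function(x, ...) {
  cat("<screening_pattern_mix> HEDIS", x$hedis_rate, "\n")
  print(round(x$proportions, 4))
  invisible(x)
}

#' Treatment-year missed work-days by stage at diagnosis
#'
#' The published figure is a single mean of 44.5 days missed across
#' treated women, with late-stage disease missing far more days; the
#' stage split itself is not published. The severity multipliers in
#' `params$days_multiplier` are rescaled so that, weighted by the
#' expected first-cycle stage-at-diagnosis mix under the base 70% HEDIS
#' pattern mix, the mean equals `days_missed_mean`. The rescaling uses
#' a fixed reference mix so that the same stage always costs the same
#' days across scenarios.
#'
#' @param params A [mammography_params()] object.
#' @return Named vector of days missed per stage.
#' @export
days_missed_by_stage <- function(params) {
  mix <- pattern_mix_for_hedis(0.70)$proportions
  sigma1 <- c(annual = 1, biennial = 1, sporadic = 0.2, none = 0)
  w <- stats::setNames(numeric(length(MAMMO_STAGES)), MAMMO_STAGES)
  for (g in MAMMO_PATTERNS) {
    q_scr <- if (g == "none") 0 else
      params$incidence_screened[[g]] * params$stage_dist_screened[[g]]
    w <- w + mix[[g]] * (sigma1[[g]] * q_scr +
      (1 - sigma1[[g]]) * params$incidence_unscreened *
        params$stage_dist_unscreened)
  }
  if (sum(w) == 0) {
    # no diagnoses are possible, so treatment-year days never accrue
    return(0 * params$days_multiplier)
  }
  ref_mix <- w / sum(w)
  scale <- params$days_missed_mean /
    sum(ref_mix * params$days_multiplier)
  params$days_multiplier * scale
}

variant_stage_dists <- function(params, variant) {
  base <- params$stage_dist_screened
  switch(variant,
         base = , fp_cost = , fp_cost_rescreen = base,
         I = lapply(base, function(q) MAMMO_STAGE_PESSIMISTIC),
         II = lapply(base, function(q)
           q + (MAMMO_STAGE_OPTIMISTIC - q) / 3),
         III = lapply(base, function(q)
           q + 2 * (MAMMO_STAGE_OPTIMISTIC - q) / 3),
         IV = lapply(base, function(q) MAMMO_STAGE_OPTIMISTIC),
         stop("unknown variant '", variant, "'; expected one of ",
              paste(MAMMO_VARIANTS, collapse = ", ")))
}

# Expected screening probability per cycle for each pattern. Only the
# sporadic pattern is probabilistic (one mammogram in five years,
# uniform phase: 1/5 of the subgroup each cycle); the rescreen variant
# inflates later-cycle sporadic screening by `rescreen_boost` times the
# expected number of prior false positives.
screening_schedule <- function(params, variant) {
  nc <- params$horizon_years
  sigma <- matrix(0, length(MAMMO_PATTERNS), nc,
                  dimnames = list(MAMMO_PATTERNS, NULL))
  sigma["annual", ] <- 1
  sigma["biennial", seq(1L, nc, by = 2L)] <- 1
  p_spor <- 1 / 5
  if (variant == "fp_cost_rescreen") {
    fp_seen <- 0
    for (t in seq_len(nc)) {
      s_t <- min(1, p_spor * (1 + params$rescreen_boost * fp_seen))
      sigma["sporadic", t] <- s_t
      fp_seen <- fp_seen + s_t *
        (1 - params$incidence_screened[["sporadic"]]) *
        params$false_positive_rate
    }
  } else {
    sigma["sporadic", ] <- p_spor
  }
  sigma
}

#' Build the mammography screening transition model and rewards
#'
#' Assembles the cycle-dependent [transition_model()] and
#' [reward_schedule()] for a given screening-pattern mix and
#' sensitivity variant. The state space is blocked by screening pattern
#' (patterns persist over the whole horizon): `Well`, stage-specific
#' remission states, progressive disease, and a shared `Dead` state.
#' Diagnosis, initial treatment, recurrence treatment, mammogram and
#' false-positive follow-up costs, treatment disutilities and
#' treatment-year employment/absence are encoded as transition rewards
#' on the corresponding probability flows.
#'
#' @param params A [mammography_params()] object.
#' @param mix A [pattern_mix_for_hedis()] result (or a HEDIS rate).
#' @param variant Sensitivity variant: `"base"`, stage-distribution
#'   variants `"I"`-`"IV"` (pessimistic to optimistic), or the
#'   false-positive variants `"fp_cost"`, `"fp_cost_rescreen"`.
#' @return List with `model`, `rewards`, `initial` and `meta` (stage
#'   distributions and day allocations actually used).
#' @export
build_mammography_model <- function(params, mix, variant = "base") {
  stopifnot(inherits(params, "mammography_params"))
  variant <- match.arg(variant, MAMMO_VARIANTS)
  if (!inherits(mix, "screening_pattern_mix")) {
    mix <- pattern_mix_for_hedis(mix)
  }
  use_fp <- variant %in% c("fp_cost", "fp_cost_rescreen")
  q_scr <- variant_stage_dists(params, variant)
  q_un <- params$stage_dist_unscreened
  sigma <- screening_schedule(params, variant)
  days_stage <- days_missed_by_stage(params)
  days_prog <- if (is.null(params$days_missed_progressive))
    days_stage[["IV"]] else params$days_missed_progressive

  live_of <- function(g) paste0(c("Well", paste0("Rem_", MAMMO_INVASIVE),
                                  "Prog"), ".", g)
  states <- c(unlist(lapply(MAMMO_PATTERNS, live_of)), "Dead")
  channels <- c("survival", "utility", "employment", "days",
                "direct_cost", "mammograms", "exits")
  nc <- params$horizon_years
  frac <- params$death_cycle_fraction
  pdo <- params$p_death_other
  pdp <- params$p_death_progression

  # ---- state rewards (identical across cycles) ----
  R <- matrix(0, length(states), length(channels),
              dimnames = list(states, channels))
  for (g in MAMMO_PATTERNS) {
    w <- paste0("Well.", g); pr <- paste0("Prog.", g)
    R[w, c("survival", "utility", "employment")] <-
      c(1, params$utility_well, params$emp_well)
    for (s in MAMMO_INVASIVE) {
      rs <- paste0("Rem_", s, ".", g)
      R[rs, c("survival", "utility", "employment")] <-
        c(1, params$utility_remission[[s]], params$emp_remission[[s]])
    }
    R[pr, c("survival", "utility", "employment")] <-
      c(1, params$utility_progressive, params$emp_progressive)
    R[pr, "days"] <- days_prog * params$emp_progressive
    R[pr, "direct_cost"] <- params$cost_recurrent
  }

  # ---- per-cycle transitions and transition rewards ----
  # paths for a newly diagnosed stage-s cancer out of the well state
  dx_paths <- function(g, s, prob) {
    if (prob <= 0) return(list())
    well <- paste0("Well.", g)
    exits <- 1 - params$emp_treatment[[s]]
    if (s == "InSitu") {
      ex_live <- c(utility = params$disutility_treatment[[s]],
                   direct_cost = params$cost_treatment[[s]],
                   employment = params$emp_treatment[[s]] - params$emp_well,
                   days = days_stage[[s]] * params$emp_treatment[[s]],
                   exits = exits)
      ex_dead <- ex_live
      ex_dead[c("utility", "days")] <- ex_dead[c("utility", "days")] * frac
      ex_dead[["employment"]] <- 0
      return(list(path(well, prob * (1 - pdo), ex_live),
                  path("Dead", prob * pdo, ex_dead)))
    }
    r_s <- params$p_remission_dx_year[[s]]
    d_s <- params$disutility_treatment[[s]]
    ex <- function(dest_emp, dest_days, dest_cost = 0) {
      c(utility = d_s,
        direct_cost = params$cost_treatment[[s]] - dest_cost,
        employment = params$emp_treatment[[s]] - dest_emp,
        days = days_stage[[s]] * params$emp_treatment[[s]] - dest_days,
        exits = exits)
    }
    # death from cancer is a within-year branch event credited with
    # part-year utility; death from other causes is a cycle-boundary
    # transition with no part-year credit (keeps the no-cancer life
    # expectancy at its geometric closed form)
    ex_dead_cancer <- c(utility = frac * (params$utility_well + d_s),
                        direct_cost = params$cost_treatment[[s]],
                        employment = 0,
                        days = days_stage[[s]] *
                          params$emp_treatment[[s]] * frac,
                        exits = exits)
    ex_dead_other <- c(direct_cost = params$cost_treatment[[s]],
                       employment = 0,
                       days = days_stage[[s]] *
                         params$emp_treatment[[s]] * frac,
                       exits = exits)
    list(
      path(paste0("Rem_", s, ".", g), prob * r_s * (1 - pdo),
           ex(params$emp_remission[[s]], 0)),
      path(paste0("Prog.", g), prob * (1 - r_s) * (1 - pdp) * (1 - pdo),
           ex(params$emp_progressive, days_prog * params$emp_progressive,
              params$cost_recurrent)),
      path("Dead", prob * (1 - r_s) * pdp, ex_dead_cancer),
      path("Dead", prob * (r_s + (1 - r_s) * (1 - pdp)) * pdo,
           ex_dead_other)
    )
  }

  transitions <- vector("list", nc)
  trans_rewards <- vector("list", nc)
  for (t in seq_len(nc)) {
    P <- matrix(0, length(states), length(states),
                dimnames = list(states, states))
    P["Dead", "Dead"] <- 1
    TR <- lapply(stats::setNames(nm = channels), function(ch)
      matrix(0, length(states), length(states),
             dimnames = list(states, states)))
    for (g in MAMMO_PATTERNS) {
      well <- paste0("Well.", g)
      s_t <- sigma[g, t]
      paths <- list()

      # screened branch: mammogram delivered, detection at the
      # pattern's screened rate, screened stage distribution
      if (s_t > 0) {
        inc <- params$incidence_screened[[g]]
        mam_ex <- c(mammograms = 1, direct_cost = params$cost_mammogram)
        fp_ex <- if (use_fp)
          c(direct_cost = params$false_positive_rate *
              params$cost_false_positive) else NULL
        add_mam <- function(p) {
          p$extras <- combine_extras(p$extras, mam_ex)
          p
        }
        nondx <- s_t * (1 - inc)
        paths <- c(paths, list(
          path(well, nondx * (1 - pdo), combine_extras(mam_ex, fp_ex)),
          path("Dead", nondx * pdo, combine_extras(mam_ex, fp_ex))
        ))
        for (s in MAMMO_STAGES) {
          paths <- c(paths, lapply(
            dx_paths(g, s, s_t * inc * q_scr[[g]][[s]]), add_mam))
        }
      }

      # unscreened branch: clinical detection, unscreened distribution
      if (s_t < 1) {
        inc_u <- params$incidence_unscreened
        nondx <- (1 - s_t) * (1 - inc_u)
        paths <- c(paths, list(
          path(well, nondx * (1 - pdo)),
          path("Dead", nondx * pdo)
        ))
        for (s in MAMMO_STAGES) {
          paths <- c(paths,
                     dx_paths(g, s, (1 - s_t) * inc_u * q_un[[s]]))
        }
      }

      row <- row_from_paths(paths, states, channels)
      row$p <- fix_row_sum(row$p, "Dead")
      P[well, ] <- row$p
      for (ch in channels) TR[[ch]][well, ] <- row$tr[, ch]

      # remission states: continued remission, recurrence (treated at
      # the recurrent-disease cost, then second remission or death)
      for (s in MAMMO_INVASIVE) {
        rs <- paste0("Rem_", s, ".", g)
        c_s <- params$p_continued_remission[[s]]
        rec_ex <- c(direct_cost = params$cost_recurrent)
        rec_dead_ex <- c(utility = frac * params$utility_remission[[s]],
                         direct_cost = params$cost_recurrent)
        paths <- list(
          path(rs, c_s * (1 - pdo)),
          path(rs, (1 - c_s) * (1 - pdp) * (1 - pdo), rec_ex),
          path("Dead", (1 - c_s) * pdp, rec_dead_ex),
          path("Dead", (c_s + (1 - c_s) * (1 - pdp)) * pdo)
        )
        row <- row_from_paths(paths, states, channels)
        row$p <- fix_row_sum(row$p, "Dead")
        P[rs, ] <- row$p
        for (ch in channels) TR[[ch]][rs, ] <- row$tr[, ch]
      }

      # progressive disease: high annual death risk; the death year
      # still incurs recurrent-treatment cost and part-year absence
      pr <- paste0("Prog.", g)
      die_cancer_ex <- c(utility = frac * params$utility_progressive,
                         direct_cost = params$cost_recurrent,
                         days = days_prog * params$emp_progressive * frac)
      die_other_ex <- c(direct_cost = params$cost_recurrent,
                        days = days_prog * params$emp_progressive * frac)
      paths <- list(
        path(pr, (1 - pdp) * (1 - pdo)),
        path("Dead", pdp, die_cancer_ex),
        path("Dead", (1 - pdp) * pdo, die_other_ex)
      )
      row <- row_from_paths(paths, states, channels)
      row$p <- fix_row_sum(row$p, "Dead")
      P[pr, ] <- row$p
      for (ch in channels) TR[[ch]][pr, ] <- row$tr[, ch]
    }
    transitions[[t]] <- P
    trans_rewards[[t]] <- TR
  }

  model <- transition_model(states, transitions, n_cycles = nc,
                            absorbing = "Dead", cycle_length = "year")
  Rarr <- array(R, dim = c(dim(R), 1L),
                dimnames = c(dimnames(R), list(NULL)))
  # part-cycle death credits are carried entirely by the transition
  # rewards above (cancer-death branches only), so the engine-level
  # death credit is disabled
  rewards <- reward_schedule(Rarr, trans_rewards,
                             death_states = "Dead",
                             death_cycle_fraction = frac,
                             death_credit_channels = character(0))
  initial <- stats::setNames(numeric(length(states)), states)
  for (g in MAMMO_PATTERNS) {
    initial[paste0("Well.", g)] <- mix$proportions[[g]]
  }
  list(model = model, rewards = rewards, initial = initial,
       meta = list(variant = variant, mix = mix,
                   stage_dist_screened = q_scr,
                   days_missed_by_stage = days_stage,
                   days_missed_progressive = days_prog,
                   screening_schedule = sigma))
}

combine_extras <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  out <- a
  for (nm in names(b)) {
    out[nm] <- (if (nm %in% names(out)) out[[nm]] else 0) + b[[nm]]
  }
  out
}

fix_row_sum <- function(p, sink) {
  resid <- 1 - sum(p)
  if (abs(resid) > 1e-9) {
    stop("internal error: row sums to ", format(sum(p), digits = 15))
  }
  p[sink] <- p[sink] + resid
  p
}

#' Run one mammography screening scenario
#'
#' Builds the model for a HEDIS rate and variant, propagates the cohort
#' over the five-year horizon, and reports per-person expectations on
#' the published scales: years on 0-5, currency per woman over the
#' horizon.
#'
#' @inheritParams build_mammography_model
#' @param hedis_rate Two-year mammography rate.
#' @param assumptions An [economic_assumptions()] object used to price
#'   missed days and workforce exits.
#' @return Object of class `mammography_outputs`: named list with
#'   `life_expectancy`, `qalys`, `employment_years`, `missed_days`,
#'   `missed_work_cost`, `medical_cost`, `mammograms`, `exits`,
#'   `turnover_cost`, and the `cohort_trace` as attribute `"trace"`.
#' @export
run_mammography_scenario <- function(params = mammography_params(),
                                     hedis_rate = 0.70,
                                     variant = "base",
                                     assumptions = economic_assumptions()) {
  built <- build_mammography_model(params, hedis_rate, variant)
  trace <- run_cohort(built$model, built$rewards, built$initial,
                      discount_rate = params$discount_rate)
  pp <- trace$per_person
  out <- list(
    life_expectancy = pp[["survival"]],
    qalys = pp[["utility"]],
    employment_years = pp[["employment"]],
    missed_days = pp[["days"]],
    missed_work_cost = absenteeism_cost(pp[["days"]], assumptions),
    medical_cost = pp[["direct_cost"]],
    mammograms = pp[["mammograms"]],
    exits = pp[["exits"]],
    turnover_cost = pp[["exits"]] * annual_turnover_cost(assumptions),
    hedis_rate = hedis_rate, variant = variant
  )
  attr(out, "trace") <- trace
  class(out) <- "mammography_outputs"
  out
}

#' @export
print.mammography_outputs <- function(x, ...) {
  cat(sprintf("<mammography_outputs> HEDIS %.0f%%, variant %s\n",
              100 * x$hedis_rate, x$variant))
  cat(sprintf("  life expectancy (0-5y): %.5f\n", x$life_expectancy))
  cat(sprintf("  QALYs:                  %.5f\n", x$qalys))
  cat(sprintf("  employment-years:       %.5f\n", x$employment_years))
  cat(sprintf("  missed-work cost:       $%.4f\n", x$missed_work_cost))
  cat(sprintf("  medical care cost:      $%.4f\n", x$medical_cost))
  invisible(x)
}

#' Compare two HEDIS screening scenarios
#'
#' Runs the model at a low and a high HEDIS rate under the same variant
#' and returns channel-by-channel per-person deltas
#' (high scenario - low scenario; savings are negative).
#'
#' @inheritParams run_mammography_scenario
#' @param low_rate,high_rate HEDIS rates to compare (`low_rate <
#'   high_rate`, or equal for a null comparison).
#' @return Data frame with one row per output (`life_expectancy`,
#'   `qalys`, `employment_years`, `missed_work_cost`, `medical_cost`,
#'   plus auxiliary rows) and columns `low`, `high`, `diff`.
#' @export
compare_hedis_scenarios <- function(params = mammography_params(),
                                    low_rate = 0.70, high_rate = 0.80,
                                    variant = "base",
                                    assumptions = economic_assumptions()) {
  if (low_rate > high_rate) stop("low_rate must be <= high_rate")
  lo <- run_mammography_scenario(params, low_rate, variant, assumptions)
  hi <- run_mammography_scenario(params, high_rate, variant, assumptions)
  outs <- c("life_expectancy", "qalys", "employment_years",
            "missed_work_cost", "medical_cost", "missed_days",
            "mammograms", "exits", "turnover_cost")
  data.frame(
    output = outs,
    low = vapply(outs, function(o) lo[[o]], numeric(1)),
    high = vapply(outs, function(o) hi[[o]], numeric(1)),
    diff = vapply(outs, function(o) hi[[o]] - lo[[o]], numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
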