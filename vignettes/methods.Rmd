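---
title: "Markov cohort models behind the employer business case for disparity reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov cohort models behind the employer business case for disparity reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hedisim)
```

## The question the package answers

Employers purchase most private health insurance in the US, and gaps
in quality of care between racial/ethnic groups inside an insured
workforce translate into costs the employer bears: direct medical
spending, absenteeism, and workforce turnover. `hedisim` quantifies
the employer-facing consequences of closing a gap in two HEDIS quality
measures:

* the **two-year mammography rate** among employed African-American
  women aged 50–65 (a typical gap is 70% vs 80%), and
* the **appropriate asthma controller-medication rate** among
  African-American adults and children with persistent asthma
  (typically 80% vs 90%).

Both questions are answered with discrete-time Markov cohort models:
state-occupancy fractions are propagated through per-cycle transition
matrices and multiplied by per-cycle rewards. Rewards live on
independent named channels — survival, utility (QALYs), employment,
days, direct cost — so each endpoint is an expectation accumulated
over the same trajectory distribution.

## The engine

A `transition_model` holds an ordered state set and one transition
matrix per cycle (cycle dependence encodes screening-pattern timing).
`run_cohort()` performs the expected-value propagation;
`run_microsim()` samples individual trajectories under *exactly* the
same law and serves as a validation oracle: for every shipped
configuration the cohort expectations agree with micro-simulation
means within three standard errors at 200,000 individuals (asserted in
the test suite).

Reward timing follows one convention throughout: **state rewards are
credited at the end of each cycle, after that cycle's transition has
resolved**, with no half-cycle correction. With a survival channel
paying 1 per live cycle, a cohort facing only the 1% annual other-cause
death hazard therefore has five-year life expectancy
$\sum_{t=1}^{5} 0.99^t = 4.86197$ — the model's no-disease ceiling.
One-off within-cycle events (a diagnosis, a treatment, an
exacerbation) are *transition rewards*: extra reward credited per unit
of probability flow along a specific transition in a specific cycle.
Where several within-cycle event paths share the same origin and
destination state, the builders attach the flow-weighted expected
extra; this leaves cohort expectations exact and keeps the
micro-simulator on the identical law.

### Death inside a cycle

Someone dying mid-cycle has lived part of it. Following the stated
convention of both models, the cycle of death accrues half
(`death_cycle_fraction = 0.5`) of the utility reward; the survival
channel counts only completed cycles, which is what pins the geometric
closed form above. In the mammography model we credit the part-cycle
utility only on *cancer*-death flows: cancer deaths are within-year
branch events (diagnosis → failed treatment → death), while
other-cause death is a boundary transition between cycles. This choice
reproduces the published ordering QALYs < life expectancy; crediting
all deaths equally reverses it. The asthma model credits all deaths
(its published rule — half a month at the pre-death utility — draws no
cause distinction). The 0.5 fraction itself is a documented default,
not a published value, and is exposed as a parameter.

No discounting is applied by default; a `discount_rate` parameter
exists and is zero.

## The mammography model

Annual cycles over five years; the cohort starts well, fully employed,
split across four persistent screening patterns (annual, biennial,
sporadic = one mammogram in five years, none). `pattern_mix_for_hedis()`
maps a HEDIS rate to this mix: the published decompositions are
returned verbatim for 70% and 80%; other rates solve the constraint
system {proportions sum to 1; biennial = 2 × annual; annual + biennial
+ 0.4 · sporadic = rate; sporadic:none ratio fixed}. The 0.4 reflects
the 2-in-5 chance that a sporadic screener's single mammogram falls in
the two-year HEDIS window. Biennial screens happen in cycles 1, 3, 5;
the sporadic screen's phase is uniform (one fifth of the subgroup per
cycle), chosen so no year is privileged.

Cancer detection: 3/1,000 per screened year for annual/biennial
patterns, 5/1,000 in the sporadic screened year, and 8/1,000
*clinically detected* in any year without a mammogram, for every
pattern. Screening acts through the **stage shift**: mammogram-detected
cancers draw an earlier stage-at-diagnosis distribution than
clinically detected ones, and stage drives everything downstream —
remission probability, recurrence, death, utility, employment,
treatment cost, missed days. The diagnosis year resolves to remission
(by stage), progressive disease, or death (progression × 0.79);
remission years continue or recur, with recurrences treated at the
recurrent-disease cost and resolving to death (0.79) or second
remission. In-situ disease returns to the well state with no
cancer-death risk; its treatment cost is unpublished and defaults to
zero.

Employment and absenteeism: each diseased state carries an employment
probability; the indirect-cost channel accrues (days missed ×
employment probability), priced at 8 h × $21.31. Only a single
cohort-mean figure (44.5 treatment-year days) is published, so the
allocation across stages uses relative severity multipliers rescaled
so the diagnosis-mix-weighted mean equals 44.5 under a fixed reference
mix (first cycle, 70% base mix) — the same stage then always costs the
same days in every scenario. The allocation itself is an assumption;
only its mean is anchored. Workforce exits (for turnover costing) are
charged once per diagnosis at (1 − treatment-year employment
probability).

Sensitivity variants I–IV replace the screened stage distributions
with points on the pessimistic→optimistic axis of the published
ranges: I is the pessimistic corner (identical to the unscreened
distribution — screening confers no stage benefit, leaving only the
detection-rate effect), IV the optimistic corner, II and III one- and
two-thirds interpolations from the base distributions toward the
optimistic corner. The exact published combinations live in a
supplementary table that is not available, so these are labelled
reconstructions, anchored by the published ordering. The
false-positive variants add $533 follow-up cost with probability 0.10
per cancer-free mammogram, and optionally a 10% relative increase in
later sporadic screening after a false positive.

### What the model reproduces, and a known gap

The screening *gains* land inside the published bands: life-expectancy
gain ≈ 0.0011 (published 0.00151), QALY gain ≈ 0.0020 (0.00238),
missed-work saving ≈ $10 (−$12.53), medical-cost saving ≈ $35
(−$37.67), with variants ordered correctly. The life-expectancy
*level* at 70% computes to 4.8414 against a published 4.85705: the
published branch probabilities (continued remission by stage with
death-given-progression 0.79) imply annual death rates of roughly
2.0%/4.7%/15%/27% by stage, while the source reports its model
realized 0.75%/3%/12.6%/26.4%. No mechanism constructible from the
published branch inputs yields both the published level and the
published gains; we keep the branch mechanism (which preserves the
gains) and document the level gap rather than calibrating toward it.
The reported stage-wise death rates are retained on the parameter
object as reference metadata.

## The asthma model

Monthly cycles, up to 60. A live state is a pair (medication status
this month, event category this month): no exacerbation, exacerbation
with an office visit, an ER/urgent-care visit, or a hospital
admission; event probabilities depend only on current medication
status, and next month's status follows a persistence mapping indexed
by this month's event. Asthma deaths occur only from ER (0.0002) and
admission (0.0014) months, plus a 0.0001 monthly other-cause hazard.

Days: adults have 21.67 work days per month available (2080 h year),
children 15 school days (180-day school year smoothed over twelve
months — the model consequently understates school-day losses during
term and overstates them in summer, with an accurate annual mean).
Events cost 3/4/7 days and $155.44/$1,080/$13,512; medication costs
$112 in every month spent in a using state. A child's missed school
day costs an employed parent one work day (`parent_workday_ratio`,
default 1).

Scenario rates hold the cohort medication-use fraction at the
scenario rate, mirroring the published constraint that overall use
stay constant over the simulation: the published persistence sets are
used for 70%, 80% and 90% (their stationary med-use fractions are
0.708, 0.806 and 0.903), and other rates are calibrated by scaling the
off-medication restart probabilities by a common factor until the
stationary fraction equals the target. `persistence = "base"` instead
keeps the base mapping at any rate, in which case the cohort fraction
drifts gradually toward 0.806 and the drift is reported, not
suppressed. Under the base mapping the fraction rises slowly from
0.80, matching the intended gradual improvement.

The monthly utilities are taken as published; they derive from per-day
utilities via a month ≈ 30/365 year convention (0.0748/0.91 ≈ 30/365
within 1%, asserted as a property test), but the published
exacerbation-month utilities cannot be re-derived exactly from the
stated day counts, so they are inputs, not derived quantities. Where
the narrative, the parameter table and the appendix disagree on
persistence values (restart after exacerbation 15% vs 6% vs 25%) or
days missed, the parameter table is canonical.

This model reproduces the published scenario table closely: cumulative
QALYs at all four rates within 0.0006, adult work days within 3 (band
±5), child school days within 1, the per-10-point work-day gain 5.58
(published 5–6), and the net direct saving $84.70 against a published
$86.50.

## Economics

`absenteeism_cost()` is days × 8 h × $21.31; `annual_turnover_cost()`
is 33% of a 2080-hour salary, $14,627. `business_case_row()` totals
direct + indirect deltas under the convention that savings are
negative (a CLI flag flips the sign for prose-style figures), and
`scale_to_population()` applies report rounding (none / integer /
nearest 50) without ever feeding rounded values back into computation.
Money prints at two decimals and rates at five; JSON bundles keep full
precision.

## Numerical choices and degenerate inputs

* Row sums are constructed exactly (the residual, at most 1e-9 and in
  practice ~1e-16, is folded into the absorbing state); validation
  tolerates 1e-9 and config-supplied distributions are normalised only
  when within 1e-6 of 1 — larger deviations are errors.
* The pattern-mix identity check uses 5e-3 because the published 80%
  decomposition itself satisfies the identity only to 2.2e-3.
* Zero incidence, zero exacerbation probabilities, equal-rate
  comparisons and one-month horizons all degrade to closed forms,
  asserted in the tests.
* The micro-simulator is deterministic given its seed and uses the
  identical reward law as the cohort evaluator, including flow-averaged
  transition rewards.

## Problem sizes

The shipped analyses are small by construction: 25 states × 5 cycles
(mammography) and 10 states × 60 cycles (asthma); every scenario runs
in milliseconds, and the oracle checks use 200,000 simulated
individuals per configuration, a size at which channel standard errors
are 10–100× smaller than the published tolerance bands.

## What passing tests do and do not show

The models emulate the published study conditions: a closed,
fully-employed cohort with homogeneous wages, persistent screening
behaviour, stage-invariant incidence within a detection mode, and
exclusive monthly event categories. They do not model screening
follow-up failures, treatment-access differences, seasonal
exacerbation patterns, presenteeism, wage heterogeneity, or horizons
beyond five years — so agreement with the published tables validates
the implementation of this decision model, not the epidemiology of
real workforces.
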