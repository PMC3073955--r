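# hedisim

Markov cohort models for the **employer business case of closing
quality-of-care disparities**, in two clinical settings tied to HEDIS
quality measures:

* **Mammography screening** — a five-year, annual-cycle model of
  employed African-American women aged 50–65. Raising the two-year
  HEDIS mammography rate (e.g. 70% → 80%) shifts the stage-at-diagnosis
  distribution of detected breast cancers toward earlier stages, which
  raises remission probability and employment and lowers treatment
  cost, absenteeism and turnover.
* **Asthma controller medications** — a monthly-cycle model (up to 60
  months) of adults and children with persistent asthma. Raising the
  appropriate-medication rate (e.g. 80% → 90%) roughly halves
  exacerbation, ER and admission probabilities for the switched
  fraction, recovering work/school days and event costs at the price
  of added medication cost.

Both models are evaluated by expectation: for cycle $t$ with
transition matrix $P_t$, occupancy $\pi_t = \pi_{t-1} P_t$, and each
reward channel $c$ (survival, utility, employment, days, direct cost)
accumulates

$$V_c \;=\; \sum_t \Big[ \pi_t\, r_c(t) \;+\; \mathrm{flow}_t \odot
T_c(t) \Big],$$

where $r_c(t)$ are end-of-cycle state rewards and $T_c(t)$ are one-off
transition rewards on specific probability flows (treatment cost and
disutility in the diagnosis year, mammogram and false-positive costs,
part-cycle utility in the cycle of death). An individual-level
Monte-Carlo simulator (`run_microsim()`) runs the identical law and
validates every shipped configuration within 3 standard errors at
n = 200,000. Companion functions convert days and exits into employer
dollars (absenteeism at 8 h × $21.31/h; turnover at 33% of a 2080-hour
salary = $14,627 per exit) and assemble the business-case comparison
table.

## Worked example

```r
library(hedisim)

run_asthma_scenario(asthma_params(), med_use_rate = 0.80)
#> <asthma_outputs> adult, 60 months, medication-use rate 80%
#>   cumulative QALYs:      4.38387
#>   attended days:         1225.55
#>   missed days:           70.11
#>   event cost:            $9271.50
#>   medication cost:       $5394.86
#>   cumulative deaths:     0.00687
```

Over five years an adult with asthma on the 80% medication-use
scenario attends ~1,226 of 1,300 possible work days and accrues 4.38
QALYs; cumulative mortality stays below 1%. Comparing scenarios and
assembling the employer table (savings print negative):

```r
build_comparison_table(
  compare_hedis_scenarios(mammography_params(), 0.70, 0.80),
  compare_med_use_scenarios(asthma_params(), 0.80, 0.90),
  compare_med_use_scenarios(asthma_params(), 0.70, 0.90))
#> <comparison_report> per-person deltas (savings negative)
#>                                  label direct_delta days_delta indirect_delta
#>    Mammography rate +10% (no turnover)      $-34.97      -0.06         $-9.95
#>  Mammography rate +10% (with turnover)      $-34.97      -0.06        $-22.56
#>    Asthma medication use +10% (adults)      $-84.70      -5.58       $-943.25
#>    Asthma medication use +20% (adults)     $-170.78     -11.25      $-1901.87
#>  total_delta turnover_included
#>      $-44.92             FALSE
#>      $-57.53              TRUE
#>    $-1027.95             FALSE
#>    $-2072.65             FALSE
```

The asthma business case dominates the mammography one by more than an
order of magnitude per person: recovered work days (5.58 per adult per
10-point rate increase, worth $943 over five years) drive it, while
the mammography case rests on small expected savings (≈$45/woman over
five years) from a low-incidence disease. Note the asthma direct
column is the *net* of event-cost savings minus added medication cost.

Parameters load from annotated YAML configs
(`default_config("mammography")`, etc.); any field can be overridden.
A thin CLI wraps the same functions:

```sh
Rscript inst/cli/hedisim.R asthma run --rate 0.80 --months 60 --out out/
Rscript inst/cli/hedisim.R sensitivity --out out/
Rscript inst/cli/hedisim.R microsim-check --model asthma --seed 7
```

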