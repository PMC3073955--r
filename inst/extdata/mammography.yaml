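# Base-case parameters of the five-year mammography screening model
# (employed African-American women aged 50-65). Provenance noted per
# field; every probability is validated on load.
model: mammography

# SEER annual incidence for African-American women mid-band (55-60)
annual_incidence: 0.003

# cancers found per mammogram year, by screening pattern: 3/1,000 in
# second screening rounds (annual, biennial), 5/1,000 for sporadic
# (one mammogram in five years) screeners
incidence_screened:
  annual: 0.003
  biennial: 0.003
  sporadic: 0.005

# cancers detected clinically, per year without a mammogram (8/1,000;
# midpoint between the sporadic screen rate and first-screen rates)
incidence_unscreened: 0.008

# stage at diagnosis for mammogram-detected cancers: Jacobellis-Cutter
# for annual/biennial screens, Yood (managed-care population) for
# sporadic screens
stage_dist_screened:
  annual:    {InSitu: 0.13, I: 0.41, II: 0.37, III: 0.07, IV: 0.02}
  biennial:  {InSitu: 0.13, I: 0.41, II: 0.37, III: 0.07, IV: 0.02}
  sporadic:  {InSitu: 0.17, I: 0.29, II: 0.40, III: 0.09, IV: 0.05}

# stage at diagnosis for clinically detected cancers (Bibb)
stage_dist_unscreened: {InSitu: 0.04, I: 0.32, II: 0.43, III: 0.13, IV: 0.08}

# probability of remission (vs progressive disease) after initial
# treatment, by stage at diagnosis
p_remission_dx_year: {I: 0.975, II: 0.94, III: 0.81, IV: 0.66}

# probability of continued remission (vs recurrence) each later year;
# printed equal to the diagnosis-year values, kept separate so either
# can be varied
p_continued_remission: {I: 0.975, II: 0.94, III: 0.81, IV: 0.66}

# probability of death in a year of recurrent or progressive disease
p_death_progression: 0.79

# annual probability of death from causes other than cancer
p_death_other: 0.01

# reported annual death rates by stage the branch probabilities were
# calibrated against (reference metadata, not used in the dynamics)
annual_cancer_death_rate: {I: 0.0075, II: 0.03, III: 0.126, IV: 0.264}

# state utilities; remission utilities also value the end of the
# diagnosis year, and treatment subtracts a within-year disutility
utility_well: 1.0
utility_remission: {I: 0.90, II: 0.85, III: 0.81, IV: 0.81}
disutility_treatment: {InSitu: 0.0, I: -0.10, II: -0.20, III: -0.25, IV: -0.25}
utility_progressive: 0.40

# employment probabilities (cohort assumed fully employed at entry;
# treatment-year and remission values from labor-force studies of
# breast-cancer survivors)
emp_well: 1.0
emp_treatment: {InSitu: 0.86, I: 0.70, II: 0.60, III: 0.50, IV: 0.40}
emp_remission: {I: 0.94, II: 0.88, III: 0.81, IV: 0.75}
emp_progressive: 0.56

# direct medical costs (USD); no published initial-treatment cost for
# in-situ disease, so 0 by default
cost_treatment: {InSitu: 0, I: 22488, II: 27213, III: 29220, IV: 31476}
cost_recurrent: 33000
cost_mammogram: 81.86          # Federal Register, 2007

# false-positive variants: follow-up cost and rate, and the relative
# increase in later mammography probability after a false positive
cost_false_positive: 533
false_positive_rate: 0.10
rescreen_boost: 0.10

# absenteeism: mean work-days missed in the treatment year across
# newly diagnosed women, with relative stage-severity multipliers
# (rescaled internally so the diagnosis-mix-weighted mean matches)
days_missed_mean: 44.5
days_multiplier: {InSitu: 0.25, I: 0.70, II: 1.00, III: 1.30, IV: 1.60}

horizon_years: 5
death_cycle_fraction: 0.5      # part-year QALY accrual in year of death
discount_rate: 0.0             # no discounting in the base case
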