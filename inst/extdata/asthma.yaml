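# Base-case parameters of the monthly asthma medication model
# (African-American adults and children/adolescents with persistent
# asthma). Provenance noted per field.
model: asthma

# baseline probability of appropriate controller-medication use
med_use_rate: 0.80

# monthly event-category probabilities by medication status; inhaled
# corticosteroids roughly halve exacerbation and admission rates, and
# ER/admission rates are doubled relative to the Paltiel model to
# reflect rates observed in African-American patients
p_exac:  {med: 0.27,   nomed: 0.53}
p_er:    {med: 0.0382, nomed: 0.0756}
p_admit: {med: 0.0035, nomed: 0.0069}

# probability of using medication next month, by this month's
# medication status and event category; constrained so the cohort
# medication-use fraction stays near the baseline rate
persistence:
  med:   {none: 0.96, exac: 0.96, er: 0.99, admit: 0.99}
  nomed: {none: 0.01, exac: 0.25, er: 0.30, admit: 0.30}

# asthma deaths occur only from ER-visit and admission months
p_death_er: 0.0002
p_death_admit: 0.0014
p_death_other: 0.0001          # monthly, all live states

# monthly QALY accruals by medication status and event category
# (derived from the per-day utilities below times days per month)
utility_month:
  med:   {none: 0.0748, exac: 0.0706, er: 0.0698, admit: 0.0649}
  nomed: {none: 0.0756, exac: 0.0712, er: 0.0704, admit: 0.0654}

# reference per-day utilities (metadata; dynamics use utility_month)
daily_utilities:
  normal_nomed: 0.92
  normal_med: 0.91
  exac_day: 0.72
  er_extra: 0.05
  admit_extra: 0.10
  med_disutility: 0.01

# days per month available: 2080 h full-time year = 260 work days =
# 21.67/month for adults; 180 school days smoothed = 15/month
days_available: {adult: 21.67, child: 15}

# days of work or school missed per month, by event category
days_missed: {none: 0, exac: 3, er: 4, admit: 7}

# direct medical costs per event (USD)
cost_event: {none: 0, exac: 155.44, er: 1080, admit: 13512}
cost_medication_month: 112

# parent work-days lost per child school-day lost
parent_workday_ratio: 1.0

death_cycle_fraction: 0.5      # half a month at pre-death utility
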