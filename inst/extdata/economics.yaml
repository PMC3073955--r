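# Employer-perspective economic assumptions.
model: economics

hourly_wage: 21.31        # Department of Labor average wage, May 2007
hours_per_day: 8
hours_per_year: 2080      # full-time work year
turnover_fraction: 0.33   # replacement cost as share of annual salary
currency_rounding: 2      # printing only; computation keeps full precision
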