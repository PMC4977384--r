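# Canonical configuration example for chfmarkov. Any section may be omitted;
# omitted sections fall back to the built-in defaults (reported via message()).
# This file spells out every section with the default values.
transitions:
- label: NYHA II or III
  p_hosp_by_state: [0.008, 0.052, 0.106, 0.121, 0.180]   # H0..H4plus, per month
  p_death_not_hospitalized: 0.007
  p_death_hospitalized: 0.100
- label: NYHA III or IV
  p_hosp_by_state: [0.008, 0.168, 0.213, 0.268, 0.334]
  p_death_not_hospitalized: 0.010
  p_death_hospitalized: 0.100
scenarios:
- label: best
  sensitivity: 0.90
  specificity: 0.90
  mortality_reduction: 0.29
  hospitalization_reduction: 0.38
  los_reduction: 0.30
- label: base
  sensitivity: 0.80
  specificity: 0.80
  mortality_reduction: 0.24
  hospitalization_reduction: 0.28
  los_reduction: 0.25
- label: worst
  sensitivity: 0.70
  specificity: 0.70
  mortality_reduction: 0.19
  hospitalization_reduction: 0.18
  los_reduction: 0.20
costs:
  cost_per_admission: 12000        # USD per CHF hospitalization
  annual_chf_outpatient: 1700      # USD per alive patient-year
  annual_non_chf: 10000            # USD per alive patient-year
  monthly_install: 15              # USD per telehealth patient-month
  monthly_monitoring: 80
  monthly_case_manager: 125
  treat_physician: 52              # USD per detected episode
  treat_nurse_visit: 135
  annual_discount_rate: 0.03
cohorts:
- label: C1                        # low risk: no prior admissions
  initial_distribution: {H0: 1.0}
  horizon_months: 60
  nyha_label: NYHA II or III
- label: C2                        # intermediate risk
  initial_distribution: {H1: 0.30, H2: 0.30, H3: 0.40}
  horizon_months: 60
  nyha_label: NYHA II or III
- label: C3                        # high risk: 4+ prior admissions
  initial_distribution: {H4plus: 1.0}
  horizon_months: 60
  nyha_label: NYHA II or III
settings:
  half_cycle: false        # full-month cost accrual for patients alive at cycle start
  efficacy_gating: sen     # hazard reductions reach only detected exacerbations
  los_gating: all          # LOS cost reduction applies to every telehealth admission
  treat_trigger: usual     # TREAT frequency driven by usual-care hazards
  discount_method: annual  # costs discounted per model year
  discount_life_years: true
  ly_convention: end       # person-time credited to cycle survivors
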