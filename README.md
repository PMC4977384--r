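# chfmarkov

Markov cohort modelling of home telehealth programs for congestive heart
failure (CHF), with a full economic layer for answering the question payers
actually ask: *for which patients, and at what monthly price, does remote
monitoring pay for itself?*

## The model

CHF progresses through recurrent hospital admissions. The model tracks a
cohort through six states — five living states `H0 … H4plus` defined by the
number of prior CHF admissions, plus an absorbing death state — in monthly
cycles. In each cycle a patient in state `H` is hospitalized with probability
`p_hosp[H]`, dies with probability `p_death_hosp` if hospitalized and
`p_death_not_hosp` otherwise, and survivors of an admission advance one state
(`H4plus` is a ceiling). Hazards come from published usual-care transition
tables for the NYHA II–III and NYHA III–IV populations.

A home telehealth program has two cost channels:

* **TEST** — recurring monitoring (install amortization + monitoring + case
  manager, $220/month at default prices), billed per alive patient-month;
* **TREAT** — an early-intervention episode ($187: physician contact + nurse
  visit) triggered by every positive monitoring test. With detection
  sensitivity `SEN` and specificity `SPE`, the per-cycle trigger probability
  for a patient whose usual-care exacerbation hazard is `p` is
  `SEN·p + (1−SPE)·(1−p)` — false positives cost real money.

Clinically, the program reduces mortality, CHF hospitalization, and hospital
length of stay (LOS) by proportional factors taken from trial meta-analysis
(base case: 24%, 28%, 25%). Under the default detection-gated convention these
reductions reach only the exacerbations the monitoring detects, so the
population hazards shrink by `SEN × reduction`; the LOS effect is priced as a
per-admission cost discount. Outcomes are discounted cost per patient, life
years, and admissions; incremental values are telehealth minus usual care
(negative = saving).

A seeded individual-level microsimulation implements the identical event
logic and serves as a stochastic oracle for the deterministic engine (and for
generating synthetic patient trajectories — the stated hazards *are* the
data-generating process).

## Worked example

```r
library(chfmarkov)

cfg <- chf_defaults()   # published hazard tables, prices, scenarios, cohorts
cmp <- compare_arms(cfg$cohorts$C2,              # 30/30/40% with 1/2/3 prior admissions
                    cfg$scenarios$base,          # SEN=SPE=0.8, 24/28/25% reductions
                    cfg$costs,
                    cfg$transitions[["NYHA II or III"]],
                    horizon_months = 12,
                    settings = cfg$settings)
cmp
#> <chf_comparison> cohort C2, scenario base, 12 months
#>   usual care:  cost $25473, 0.88 LY, 1.23 admissions
#>   telehealth increment: -2832 USD (saving $2832), +0.030 LY, -0.274 admissions

break_even_fee(cfg$cohorts$C2, cfg$scenarios$base, cfg$costs,
               cfg$transitions[["NYHA II or III"]], 12, cfg$settings)
#> [1] 471.6999
```

Read: over one year, an intermediate-risk patient on usual care costs
$25,473 and has 1.23 expected admissions; telehealth saves $2,832 of that,
gains 0.03 discounted life years, and averts 0.27 admissions. The monitoring
bundle could cost up to ~$472/month (instead of $220) before the saving
vanishes.

`basecase_table()` reproduces the full cohort × horizon comparison,
`sweep_efficacy()` / `sensitivity_grid()` the one- and two-way sensitivity
analyses, `break_even_table()` the break-even fee matrix, and
`lifetime_validation()` / `national_burden()` the two validation runs.
`run_basecase()`, `run_sensitivity()` and `run_validation()` write CSV/JSON
outputs with a run manifest; `inst/cli/chfmarkov.R` is a command-line wrapper
over them. All parameters can be overridden from a YAML file
(`read_chf_config()`; schema in `inst/extdata/config-example.yaml`).

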