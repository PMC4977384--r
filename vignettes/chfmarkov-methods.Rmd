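---
title: "Methods: a Markov cohort model of CHF telehealth economics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model of CHF telehealth economics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chfmarkov)
```

## The disease model

Congestive heart failure is modelled as a six-state Markov chain in monthly
cycles: living states `H0`–`H4plus` count prior CHF hospital admissions —
admission history being the dominant predictor of subsequent risk — and
`death` is absorbing. Within a cycle, events resolve in a fixed order:

1. **Hospitalization** with probability `p_hosp[H]`, increasing in `H`
   (defaults 0.008–0.180/month for the NYHA II–III population, 0.008–0.334
   for NYHA III–IV).
2. **Death**, conditional on hospitalization status: 0.100 per admission
   event, 0.007 (NYHA II–III) or 0.010 (NYHA III–IV) per month otherwise.
3. **Progression**: survivors of an admission advance one state; `H4plus` is
   a ceiling. There are no recovery transitions — the chain never moves to a
   lower admission count.

This ordering follows from the hazard table's structure (death rates are
reported split by hospitalization status), not from a competing-risks
formulation; the in-hospital death probability is interpreted per admission
event, since length of stay is not a state. `run_horizon()` propagates a
cohort's probability mass exactly; `step_cycle()` is a single transition with
expected admissions `Σ m·p_h` and expected deaths
`Σ m·[p_h·p_dh + (1−p_h)·p_dnh]`.

## The telehealth efficacy pathway

An efficacy scenario bundles five fractions: detection sensitivity and
specificity of the home monitoring TEST, and proportional reductions in
mortality (base 24%), CHF hospitalization (28%), and hospital length of stay
(25%). Best/base/worst scenarios (90/90/29/38/30, 80/80/24/28/25,
70/70/19/18/20, in percent) ship as defaults.

**Detection gating** (`efficacy_gating`, default `"sen"`). The causal chain
is monitor → detect → treat early → avoid/attenuate the admission; a missed
exacerbation (false negative) receives usual care. The package therefore
applies the mortality and hospitalization reductions at population level as
`SEN × reduction`; `"none"` applies the raw reductions to everyone. The
shipped default was selected by calibrating against the published base-case
results the defaults are meant to reproduce: the printed incremental
admissions and life years — quantities untouched by any cost convention —
match the detection-gated dynamics across all nine cohort × horizon cells to
their printed precision, and overshoot by roughly 1/SEN without gating.
Mortality reduction applies to both death probabilities (all-cause risk
ratio). The efficacy assumption is time-constant; time-varying effectiveness
is out of scope.

An all-zero scenario (`null_efficacy()`) makes the telehealth arm's clinical
trajectory identical to usual care, which the tests assert to machine
precision.

## Cost accounting

All prices are nominal 2013 USD, payer perspective, no indirect costs. Per
cycle and per initial patient:

| channel | usual care | telehealth |
|---|---|---|
| admission | `E[admissions] × $12{,}000` | same × LOS multiplier |
| CHF outpatient | alive × $1,700/12 | same |
| non-CHF care | alive × $10,000/12 | same |
| TEST | — | alive × $220 ($15 + $80 + $125) |
| TREAT | — | alive × `[SEN·p_ex + (1−SPE)(1−p_ex)] × $187` |

Annual figures accrue uniformly at one twelfth per month (the standard cohort
convention; nothing in the source material suggests otherwise). Admission
costs are billed in the cycle of the event, including for patients who die
during the admission. Patients alive at cycle start accrue the full month's
fixed costs (`half_cycle = TRUE` switches to the half-cycle-corrected
average; default off).

**TREAT trigger** (`treat_trigger`, default `"usual"`). The monitoring system
tests for exacerbations that would occur absent intervention, so `p_ex` is
the occupancy-weighted usual-care hospitalization hazard of the telehealth
arm's living states; `"adjusted"` uses the post-reduction hazards instead.
TREAT is billed on every positive test, including averted admissions.

**LOS pricing** (`los_gating`, default `"all"`). The LOS reduction is priced
as a per-admission cost discount; per-day accounting is out of scope. Under
`"all"`, every telehealth admission is billed at `1 − los_reduction`; under
`"sen"` only the detected share is (with the detected share computed
consistently with the hazard gating, `SEN(1−hr)/(1−SEN·hr)`). Calibration
against the published base-case costs selects `"all"`: with detection-gated
hazards plus per-detection LOS pricing the one-year savings fall ~20% short
of the published values, while `"all"` reproduces them within ~2%.

**Discounting** (`discount_method`, default `"annual"`; rate 0.03/year).
`"monthly"` is the end-of-cycle convention `(1+r)^(−t/12)`; `"annual"` groups
cycles into model years and discounts year *k* by `(1+r)^−(k−1)`. The annual
convention reproduces the published one-year dollar figures essentially
exactly (they are undiscounted in year 1), and improves the three-year
figures; it is the calibrated default.

**Life years** (`ly_convention`, default `"end"`; `discount_life_years`,
default `TRUE`). Person-time is credited to patients who survive the cycle
and discounted at the cost rate with monthly granularity. This is the one
convention set under which all published life-year values (absolute and
incremental) are matched within ±0.01; undiscounted start-of-cycle counting
— arguably the more natural reading, and available via the flags — runs up
to 0.3 LY higher at five years. Life years are never utility-weighted:
QALYs are out of scope.

## Analyses

* `compare_arms()` runs both arms from identical initial conditions; the
  three shipped cohorts are C1 (all mass on `H0`), C2 (0.30/0.30/0.40 on
  `H1`/`H2`/`H3`), C3 (all mass on `H4plus`), all NYHA II–III. Multi-year
  results are cumulative totals at 12/36/60 cycles.
* `sweep_efficacy()` scales one reduction parameter by factors in [0.5, 1].
  Two robust directional facts: savings shrink as the LOS reduction is scaled
  down, and grow as the mortality reduction is scaled down (survivors keep
  accruing costs).
* `sensitivity_grid()` varies the per-admission cost and a flat monthly fee
  that replaces the whole TEST bundle (TREAT prices stay fixed). Incremental
  cost is affine in both, which the tests verify.
* `break_even_fee()` exploits that affinity: the discounted alive
  patient-months of the telehealth arm are the exact slope of total cost in
  the fee, so the zero of incremental cost is closed-form. Agreement with
  root bracketing to <$0.01 is an acceptance property. `NA` means the program
  is cost-incurring even at a zero fee ("never").
* `lifetime_validation()` (240 cycles, new-onset cohort, usual care) and
  `national_burden()` (12 cycles, prevalence-weighted cohort
  70.7/10.3/4.4/3.3/11.3% over `H0`–`H4plus`, scaled to 5M patients) are the
  two external-benchmark runs. The burden counts CHF-attributable costs only
  — admissions plus CHF outpatient care — since the non-CHF channel is not
  part of the disease's direct burden.

## The microsimulation oracle

`simulate_cohort()` draws individual patients under the identical event logic
and cost rules. Design choices:

* **Stream layout.** One seeded stream; patient *i* consumes the *i*-th
  contiguous block of `1 + 3·cycles` uniforms (initial state; per cycle:
  hospitalization, death, test). Growing `n` appends patients without
  reshuffling existing ones, and identical seeds give bit-identical output.
* **Common random numbers.** With an efficacy scenario, both arms reuse the
  same uniforms. An *exacerbation* is a hospitalization event under the
  usual-care hazard draw; the telehealth arm admits only when the same draw
  also clears the reduced hazard, so the averted-admission subpopulation is
  well defined and paired incremental estimates have small variance.
* **Detection-mediated benefit.** The cycle's test draw decides detection;
  detected patients face the reduced hazards, undetected ones the usual-care
  hazards — the individual-level counterpart of the `SEN × reduction`
  population gating, with the same expectation.

The microsimulation doubles as the package's synthetic-data generator. It
emulates exactly the stated model: state-dependent monthly hazards, constant
efficacy, homogeneous patients within a state. It does **not** emulate
patient covariates (age, sex, NYHA mixing), time-varying adherence, seasonal
exacerbation patterns, or payer-mix heterogeneity — so agreement between
engine and simulation validates the implementation, not the model's fidelity
to any real population.

## Numerical choices and problem sizes

Probability conservation is asserted at 1e-10 per cycle and holds to ~1e-15;
cohort masses are validated to sum to 1 within 1e-12 (weights for the burden
cohort within 1e-9, matching their three-digit printed precision). Break-even
roots are reported at full precision and compared to bisection at $0.01.
Degenerate inputs are well-defined: an all-dead cohort accrues nothing, a
zero-hazard cohort is static, a zero-fee null-efficacy program is exactly
cost-neutral.

The test suite exercises the oracle at n = 200,000 patients × 12 cycles for
the engine-agreement check (a few seconds, single core; paired increments
have standard errors of ~$19 on a ~$2,800 quantity) and n = 1,000–100,000
for the 1/√n occupancy-convergence property; these sizes put Monte Carlo
error well below the effects being checked.

## Known limitations

* The hazard table gives ranges for some cells (e.g. in-hospital death
  0.07–0.10); the point defaults are the printed baseline values, and
  sampling within ranges is not implemented.
* The 20-year lifetime benchmark is reproduced to ~6% but not exactly under
  any tested combination of the discounting and accrual levers; the residual
  is documented rather than tuned away, as is the near-zero low-risk
  break-even cell that the published table reports as "never".
* Costs are nominal 2013 USD with no inflation adjustment; no QALYs, no
  indirect costs, no per-day LOS accounting, no probabilistic sensitivity
  analysis (one- and two-way deterministic only).
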