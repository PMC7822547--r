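---
title: "A Markov microsimulation of diabetic foot ulcer care under two dressing strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov microsimulation of diabetic foot ulcer care under two dressing strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfusim)
```

## The model

`dfusim` implements a discrete-time, state-transition microsimulation of the
natural history of a diabetic foot ulcer (DFU) under two wound-care
strategies: an active TLC-NOSF dressing and a neutral contact-layer
dressing. Five health states are modelled — uninfected ulcer, closed
(healed) ulcer, infected ulcer, amputation, death — with monthly cycles.
Every patient starts with an uninfected ulcer. At the end of each cycle one
categorical draw resolves the competing transitions out of the current
state:

* uninfected → closed (healing, the only strategy-specific probability:
  0.091/month for the TLC-NOSF dressing, 0.058/month for the neutral one),
  uninfected → infected (0.036), uninfected → death;
* closed → uninfected (recurrence, 0.014), closed → death;
* infected → uninfected (resolution, 0.082), infected → amputation (0.011),
  infected → death;
* amputation → death (0.120); amputation is otherwise absorbing (no
  post-amputation state — a conservative simplification for the active
  strategy, which produces fewer amputations);
* death is absorbing.

State-specific monthly death probabilities (0.009 for the ulcer states,
0.120 post-amputation) are combined with age- and sex-dependent background
mortality as independent competing hazards,
`1 - (1 - p_state)(1 - p_background)`. Whether the published state-specific
values already contain background mortality is not stated in the source
material; the configuration toggle `state_death_includes_background`
switches to using them alone, and an all-zero life table
(`zero_life_table()`) isolates the printed transition inputs entirely.

Rewards accrue for the state occupied during a cycle; the transition takes
effect at cycle end; there is no half-cycle correction. Per cycle a patient
accrues

* one *life-month without DFU* if in the closed state (a toggle
  `ly_wo_dfu_counts_amputation` optionally counts amputation time as well;
  the default counts closed time only),
* `utility(state)` quality-adjusted life-months (utilities 0.75 uninfected,
  0.84 closed, 0.70 infected, 0.64 amputation, 0 dead),
* the state's monthly cost (EUR 2019), drawn between the outpatient and
  inpatient tariff by a per-state Bernoulli hospitalisation probability.

All three are discounted at `(1 + r)^(-cycle/12)` with `r = 2.5%` per year.
The base-case horizon is 480 cycles (40 years, effectively lifetime for a
cohort with mean age 64); patients alive at the horizon are censored there.

## Parameters that matter

| Parameter | Unit | Default | Why |
|---|---|---|---|
| healing probability | /month | 0.091 / 0.058 | strategy efficacy, drives everything |
| recurrence | /month | 0.014 | pulls healed patients back |
| infection / resolution / amputation | /month | 0.036 / 0.082 / 0.011 | complication pathway |
| state and post-amputation mortality | /month | 0.009 / 0.120 | survival |
| discount rate | /year | 0.025 | present-value weighting |
| horizon | cycles | 480 | lifetime at baseline age 64 |
| monthly state costs | EUR 2019 | see packaged config | cost outcomes |
| p_hospital (uninfected, infected) | /cycle | 0.10, 0.45 | inpatient/outpatient mix |

Two published healing parameterisations exist side by side in the source
tables: the monthly transition row (0.091/0.058) and a separate
"probability of healing" row (0.068/0.044). The engine uses the former
verbatim; the latter is exposed as the alternative sensitivity rows
`p_heal_tlc_alt` / `p_heal_control_alt` so its consequences can be explored
without changing the base case. The two are not mutually consistent — the
published one- and two-year effectiveness results are closer to what the
lower values produce — and this unresolved tension is the main reason the
package's effectiveness levels sit somewhat above the published point
estimates while incremental results (gains, dominance) are robust.

The hospitalisation probabilities are an explicit assumption: the source
model defers its inpatient/outpatient mix to unpublished supplementary
material. The defaults (0.10/cycle for uninfected, 0.45/cycle for infected
ulcer months) encode the clinical judgement that uncomplicated ulcers are
mostly managed in ambulatory care with nurse visits while infection
commonly triggers admission. `calibrate_hospital_mix()` refits both
probabilities (bounded to [0,1]) against target lifetime costs using the
deterministic oracle; with the published lifetime totals as targets the fit
ends at the upper boundary — those totals exceed what the published monthly
state costs can generate over the survival implied by the published QALYs —
and the helper reports this rather than hiding it. Cost-side conclusions
should therefore be read as incremental (sign and ordering), not as levels.

## Synthetic inputs

Two inputs of the original analysis are not published and are generated
synthetically:

**Baseline cohort.** Age is drawn from a normal distribution (mean 64.2,
SD 11.2 years) truncated to [18, 100]; sex is Bernoulli with 86% men; the
wound-duration category gets weights 0.20/0.36/0.26/0.18 for ≤2 / 3–5 /
6–11 / >11 months, chosen to match the published marginals (median 5
months; 56% under 6 months). The generator is an inverse-CDF transform of
uniform streams, so demographic sensitivity branches (e.g. shifting the
mean age) re-use the same underlying draws. BMI, HbA1c, wound grade and
area are reported descriptively in the source but do not enter the model,
and are not generated.

**Background mortality.** A Gompertz–Makeham life table stands in for the
national all-cause table: annual hazard `a + b·exp(c·age)` per sex with
`c = 0.085`/year (mortality doubling roughly every 8 years), Makeham terms
2e-4 (men) and 1e-4 (women), and `b` anchored so annual mortality at age 64
is 1.5% for men and 0.85% for women — the order of magnitude of recent
French statistics. The monthly probability is `1 - exp(-hazard/12)`,
tabulated by integer age (lookup at `floor(age)`; age advances 1/12 year
per cycle) and forced to 1 at the maximum age. A real life table can be
substituted through `read_life_table()`.

Because cohort and life table are synthetic, passing tests demonstrate the
mechanics and the incremental logic of the model on realistic inputs; they
do not validate absolute survival or cost levels against French registry
data.

## Randomness and common random numbers

All randomness for a run derives from one master seed:
`make_model_streams()` draws the cohort-profile uniforms and one
patient-by-cycle matrix each for transition and hospitalisation draws. Row
`i` is patient `i`'s substream. Re-using one stream object across
strategies, sensitivity branches, horizons and subgroups implements common
random numbers; with equal healing probabilities in both arms the
incremental effectiveness is then exactly zero — the model's internal
validity check, asserted in the test suite. The categorical draw partitions
the unit interval death-first, then the outgoing edges in diagram order,
then "remain"; the order is a convention and does not affect the marginal
probabilities.

## Deterministic oracle

`cohort_expectation()` propagates the occupancy distribution forward
through the same transition structure, with hospitalisation handled in
expectation and entry into the amputation state tracked as an auxiliary
flow so the admission-cycle cost is timed exactly as in the simulation. It
involves no random numbers and serves as an independent cross-check: the
test suite requires microsimulation means to agree with the oracle within
three standard errors at n = 10,000 for effectiveness, cost and amputation
probability.

## Sensitivity analyses

*Deterministic (tornado).* Each parameter in the published ranges table is
set to its lower and upper bound in turn (dressing unit prices −50%/+20%,
most others ±30%), with two full two-arm runs per bound under common random
numbers; the swing is the absolute change of the selected incremental
outcome. Sorting is stable on ties. Because the engine consumes aggregated
monthly state costs while the ranges vary unit prices, a mapping translates
price changes into cost-cell perturbations: each item has a monthly
multiplicity (dressings/month per state derived from the arm cost
differences — 27.5 uninfected, 33.3 infected, roughly daily changes; 26
nurse visits/month; biological tests and antibiotics once per infected
month; stay-length × daily-cost for the inpatient infected cell; surgery
cost on the inpatient amputation cell), and deltas apply additively,
floored at zero. This mapping is a documented artifact decision; under it
the largest cost swings come from the healing probabilities (EUR 15–20k),
while the TLC unit-price row swings about EUR 3k — the source reports
roughly EUR 17k for that row, which would require an implausible number of
dressings per month under any additive reading of the published tables.

*Probabilistic.* Parameters (transition probabilities, healing rates, cost
items — not demographics or utilities) are drawn independently and
uniformly over their deterministic ranges, once per outer replicate; the
inner loop simulates both arms with common random numbers. The default is
1,000 × 1,000; the acceptance script uses a scaled 100 × 200 design. Note
that the two arms' published healing ranges overlap ([0.064, 0.118] vs
[0.041, 0.075]); under independent uniform sampling some replicates
therefore reverse the efficacy ordering, and the dominant-quadrant fraction
is below 1 (≈0.7–0.85) — reproducing the source's claim of 100% dominance
would require a correlation or ordering structure it does not state. The
acceptability curve reports, per willingness-to-pay value on a grid
(default 0–100,000 EUR/QALY in steps of 1,000), the fraction of replicates
in which each strategy maximises net monetary benefit; ties go to the
intervention.

*Subgroups.* Wound duration at baseline affects only which healing
probabilities are used (its only published effect). The packaged
per-subgroup healing values are synthetic — the trial reports them only
graphically — monotone in duration, and serve the qualitative claim that
earlier treatment yields larger gains.

## Numerical choices and degenerate inputs

* Probabilities are validated to [0,1] and per-state outgoing mass to ≤ 1
  (residual mass = remain); violations name the state and excess.
* A period-to-cycle conversion `1 - (1-P)^(1/T)` is provided for reading
  trial-level closure rates; `P = 1` is rejected (infinite rate).
* `sd_age → 0` collapses the age distribution to the mean; `sd_age ≤ 0`
  errors.
* All-dead cohorts short-circuit the cycle loop; occupancy is padded with
  the death state so conservation holds at every cycle.
* Life-table lookups clamp at the maximum age inside the engine (where the
  terminal probability is 1), while the exported lookup errors outside the
  table range.
* Costs perturbed below zero by a sensitivity branch are floored at zero.
* Problem sizes used by the packaged checks: 1,000 patients/arm for
  reproduction runs, 10,000 for oracle agreement, 100 × 200 for the scaled
  probabilistic analysis — sizes at which Monte-Carlo error is well below
  the published tolerances being tested.

## Known limitations

* No post-amputation state, re-amputation, or individual covariate effects
  on transitions beyond age/sex (mortality) and wound-duration subgroup
  (healing).
* Absolute cost levels depend on the assumed hospitalisation mix; only
  incremental cost conclusions are robust.
* The life table and subgroup healing inputs are synthetic stand-ins.
* Effectiveness levels inherit the unresolved tension between the two
  published healing parameterisations discussed above.
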