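# dfusim

A Markov microsimulation of diabetic foot ulcer (DFU) care, built to assess
the cost-effectiveness and cost-utility of an active TLC-NOSF wound dressing
against a neutral dressing from a French collective perspective. It is aimed
at health-economics researchers who want a transparent, scriptable,
fully-testable re-implementation of a published Excel/VBA model: every input
is a plain-text configuration, every analysis is a function, and a
deterministic expectation oracle cross-checks the Monte-Carlo engine.

## The model in brief

Patients move monthly between five states — uninfected ulcer `U`, closed
ulcer `C`, infected ulcer `I`, amputation `A`, death `D` — starting in `U`.
Per cycle `t` a patient in state `s` accrues discounted rewards

```
LY_w/DFU += 1{s = C} · (1+r)^(-t/12) / 12
QALY     += u(s)     · (1+r)^(-t/12) / 12
Cost     += c(s, inpatient?) · (1+r)^(-t/12)
```

with utilities `u = (0.75, 0.84, 0.70, 0.64, 0)`, monthly costs by care
setting (EUR 2019), discount rate `r = 2.5%`/year, and then transitions with
the published monthly probabilities (healing 0.091 vs 0.058 per strategy;
infection 0.036; resolution 0.082; amputation 0.011; state-specific death
0.009/0.120 combined with an age- and sex-indexed background life table as
independent hazards). Incremental results are summarised as
`ΔLY_w/DFU`, `ΔQALY`, `ΔCost`, with ICER/ICUR reported only in trade-off
quadrants and a dominance label otherwise. One-way deterministic sensitivity
analysis (tornado), uniform probabilistic sensitivity analysis with
cost-utility acceptability curves, and wound-duration subgroup runs are
built in. The background mortality table and the baseline cohort are
synthetic generators standing in for unpublished inputs; see the methods
vignette (`vignettes/dfu-markov-model.Rmd`) for every assumption.

## Worked example

```r
library(dfusim)

params <- builtin_basecase()          # packaged published inputs
lt     <- make_life_table()           # synthetic background mortality
res    <- run_two_arm(params, n = 1000, seed = 20190101, lt = lt)
res$comparison
```

```
Incremental comparison (tlc_nosf - control), n = 1000 per arm
  delta LY w/o DFU : +0.72 years
  delta QALY       : +0.23 years
  delta cost       : -8235 EUR
  dominance        : intervention-dominant
```

The active dressing yields about eight more months without an open ulcer,
a quarter of a QALY, and saves money — it *dominates* the neutral dressing,
so no cost-effectiveness ratio is reported. Per-arm levels sit in
`res$tlc_nosf$mean` / `res$control$mean` (this seed: 4.18 vs 3.46 LY
without DFU; 4.78 vs 4.56 QALYs; EUR 42,087 vs 50,322), amputations in
`amputations_per_100()` (6 vs 8 per 100 patients). The numbered scripts
under `analysis/` run the full study — base case and 1/2/4-year horizons,
tornado, probabilistic analysis, subgroups — and write their tables with
run manifests under `results/`:

```sh
Rscript analysis/01_base_case.R --seed 20190101 --n 1000
Rscript analysis/02_dsa_tornado.R
Rscript analysis/03_psa_ceac.R --outer 1000 --inner 1000
Rscript analysis/04_subgroups.R
```

## Files

- `R/` — parameter schema and I/O, synthetic cohort and life-table
  generators, simulation engine and deterministic oracle, incremental
  economics, sensitivity analyses, report writers.
- `inst/extdata/basecase_fr_2019.yaml` — the packaged base case (published
  inputs plus flagged assumptions).
- `analysis/` — numbered drivers reproducing the study's analyses.
- `tests/testthat/` — unit, property and reproduction tests.
- `vignettes/dfu-markov-model.Rmd` — the methods vignette.
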