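Package: dfusim
Title: Markov Microsimulation for Cost-Effectiveness of Diabetic Foot Ulcer Dressings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level Markov microsimulation of diabetic foot ulcer (DFU)
    progression under two dressing strategies (an active TLC-NOSF dressing versus
    a neutral dressing), with monthly cycles over a lifetime horizon. Computes
    discounted life-years without DFU, quality-adjusted life-years, costs and
    amputations; incremental cost-effectiveness/cost-utility ratios with dominance
    classification; one-way deterministic sensitivity analysis (tornado), uniform
    probabilistic sensitivity analysis with cost-utility acceptability curves, and
    subgroup analysis by wound duration. Includes a deterministic cohort-expectation
    oracle, a synthetic Gompertz-Makeham background-mortality table, and a
    synthetic baseline-cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
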