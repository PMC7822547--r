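# Base-case model parameters: TLC-NOSF vs neutral dressing for diabetic foot
# ulcers, French collective perspective, EUR 2019, monthly cycles.
# Keys carry explicit units. Unknown keys are rejected by the loader.
horizon_cycles: 480            # 40 years x 12 monthly cycles
seed: 20190101

discount:
  annual_rate: 0.025           # proportion per year, applied to costs and effects

transitions:                   # shared monthly transition probabilities
  p_recur: 0.014               # closed ulcer -> uninfected ulcer (recurrence)
  p_infect: 0.036              # uninfected ulcer -> infected ulcer
  p_resolve: 0.082             # infected ulcer -> uninfected ulcer
  p_amp: 0.011                 # infected ulcer -> amputation
  p_death_uninf: 0.009         # uninfected ulcer -> death
  p_death_inf: 0.009           # infected ulcer -> death
  p_death_closed: 0.009        # closed ulcer -> death
  p_death_amp: 0.120           # amputation -> death

strategies:
  tlc_nosf:
    name: "TLC-NOSF dressing"
    p_heal: 0.091              # monthly probability uninfected -> closed
    dressing_unit_price_eur: 7.99
    costs_eur_per_month:
      uninfected: {outpatient: 1011, inpatient: 4209}
      closed:     {outpatient: 0,    inpatient: 0}
      infected:   {outpatient: 2005, inpatient: 6516}
      amputation: {outpatient: 337,  inpatient: 23560}
  control:
    name: "Neutral dressing"
    p_heal: 0.058
    dressing_unit_price_eur: 3.04
    costs_eur_per_month:
      uninfected: {outpatient: 875,  inpatient: 4188}
      closed:     {outpatient: 0,    inpatient: 0}
      infected:   {outpatient: 1840, inpatient: 6486}
      amputation: {outpatient: 330,  inpatient: 23410}

# Per-cycle probability that an ulcer state is managed as an inpatient.
# ASSUMPTION: the inpatient/outpatient mix is not published at the monthly
# level; these defaults are a clinical judgement (uncomplicated ulcers are
# mostly ambulatory; infection commonly triggers admission) and can be
# refitted with calibrate_hospital_mix().
p_hospital:
  uninfected: 0.10
  infected: 0.45

utilities:                     # annual-equivalent preference weights
  uninfected: 0.75
  closed: 0.84
  infected: 0.70
  amputation: 0.64
  dead: 0.0

cohort:
  mean_age_years: 64.2
  sd_age_years: 11.2
  proportion_men: 0.86
  age_min_years: 18
  age_max_years: 100
  # Category weights chosen consistent with the published marginals
  # (median duration 5 months; 56% < 6 months, 44% >= 6 months).
  wound_duration_weights:
    le_2mo: 0.20
    3_5mo: 0.36
    6_11mo: 0.26
    gt_11mo: 0.18

# Cost-component multiplicities used only by the sensitivity-analysis
# mapping from unit prices/costs to the aggregated monthly state costs.
# Dressings/month derived from the outpatient arm cost differences divided
# by the unit-price difference (~daily dressing change).
cost_components:
  dressings_per_month:
    uninfected: 27.47
    infected: 33.33
  nurse_visits_per_month: 26
  hospital_stay_days_infected: 6.10
  hospital_day_cost_infected_eur: 899
  biological_tests_eur_per_month: 137
  antibiotics_eur_per_month: 458
  amputation_surgery_eur: 7450
  nurse_visit_eur: 14.0
  unit_price_tlc_eur: 7.99
  unit_price_control_eur: 3.04

# Model-structure toggles (assumptions made explicit).
options:
  state_death_includes_background: false  # false: combine state-specific and
                                          # background mortality as independent hazards
  ly_wo_dfu_counts_amputation: false      # false: only closed-ulcer time counts

# SYNTHETIC subgroup healing probabilities by wound duration at baseline.
# The trial reports this only graphically; these illustrative values keep the
# qualitative pattern (earlier treatment -> larger healing advantage).
subgroups:
  le_2mo:  {p_heal_tlc: 0.120, p_heal_control: 0.062}
  3_5mo:   {p_heal_tlc: 0.095, p_heal_control: 0.060}
  6_11mo:  {p_heal_tlc: 0.070, p_heal_control: 0.055}
  gt_11mo: {p_heal_tlc: 0.060, p_heal_control: 0.055}
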