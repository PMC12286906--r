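# Base-case parameters for the dependence-state Markov cohort model.
# Monetary values are GBP, cost-year 2019/20. Cycle length is 3 months.
entry_distribution:
  low: 0.60
  moderate: 0.24
  high: 0.10
  dead: 0.06
transitions:
  low_to_moderate: 0.15
  moderate_to_high: 0.07
  death_low: 0.02
  death_moderate: 0.038
  death_high: 0.05
costs:
  low: 1738.0
  moderate: 3239.0
  high: 8510.0
  death_event: 3519.0
utilities:
  low: 0.788
  moderate: 0.750
  high: 0.714
  dead: 0.0
settings:
  horizon_years: 10
  cycle_length_years: 0.25
  discount_rate_costs: 0.035
  discount_rate_qalys: 0.035
  entry_age: 80
  cohort_size: 1000
  first_year_undiscounted: true
  discount_method: one_step
  include_final_row: true
  half_cycle_correction: false
  intervention_denominator: cohort
intervention:
  effect: 0.025
  per_person_cost: 570.0
  subgroup_only: false
  mode: relative
scenarios:
  effects: [0.025, 0.05, 0.075, 0.10]
  horizons: [10, 5]
  intervention_costs: [100, 250, 570, 1000, 2500]
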