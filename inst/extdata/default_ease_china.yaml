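# Default model inputs: Chinese healthcare perspective, 2023 CNY.
# Point values with 95% ranges and PSA distribution family per block.
mrs_distribution:
  # 3-month modified Rankin Scale distribution in the control arm (EASE trial)
  mrs0: {value: 0.116, low: 0.080, high: 0.152}
  mrs1: {value: 0.211, low: 0.165, high: 0.257}
  mrs2: {value: 0.175, low: 0.132, high: 0.218}
  mrs3: {value: 0.231, low: 0.184, high: 0.278}
  mrs4: {value: 0.112, low: 0.077, high: 0.148}
  mrs5: {value: 0.092, low: 0.060, high: 0.125}
  mrs6: {value: 0.063, low: 0.035, high: 0.090}
risk_ratios:
  # Risk ratio of each mRS category, argatroban vs control, with 95% CI
  rr0: {value: 1.63, low: 1.10, high: 2.40}
  rr1: {value: 0.99, low: 0.72, high: 1.34}
  rr2: {value: 0.92, low: 0.64, high: 1.32}
  rr3: {value: 1.07, low: 0.81, high: 1.43}
  rr4: {value: 0.90, low: 0.56, high: 1.43}
  rr5: {value: 0.58, low: 0.32, high: 1.05}
  rr6: {value: 0.64, low: 0.32, high: 1.30}
probabilities:
  p_sich_argatroban: {value: 0.009, low: 0.0, high: 0.020}
  p_sich_control: {value: 0.007, low: 0.0, high: 0.018}
  # annual incidence of recurrent stroke among Chinese stroke survivors
  annual_recurrence: {value: 0.112, low: 0.096, high: 0.128}
  # per-event case fatality of a recurrent stroke
  recurrence_case_fatality: {value: 0.21, low: 0.189, high: 0.232}
hazard_ratios:
  # non-stroke death hazard ratio vs general population, by alive mRS state
  hr0: {value: 1.00, low: 1.00, high: 1.20}
  hr1: {value: 1.00, low: 1.00, high: 1.20}
  hr2: {value: 1.11, low: 1.00, high: 1.30}
  hr3: {value: 1.27, low: 1.02, high: 1.52}
  hr4: {value: 1.71, low: 1.37, high: 2.05}
  hr5: {value: 2.37, low: 1.90, high: 2.84}
mortality_table:
  # annual background mortality, China Health Statistical Yearbook age bands
  - {age_low: 66, age_high: 70, annual_probability: 0.01266}
  - {age_low: 70, age_high: 75, annual_probability: 0.02159}
  - {age_low: 75, age_high: 80, annual_probability: 0.03731}
  - {age_low: 80, age_high: 85, annual_probability: 0.0634}
  - {age_low: 85, age_high: .inf, annual_probability: 0.1512}
utilities:
  u0: {value: 0.95, low: 0.94, high: 0.96}
  u1: {value: 0.89, low: 0.87, high: 0.96}
  u2: {value: 0.67, low: 0.54, high: 0.83}
  u3: {value: 0.44, low: 0.29, high: 0.60}
  u4: {value: 0.16, low: 0.09, high: 0.23}
  u5: {value: 0.10, low: 0.00, high: 0.21}
  # utility during a cycle with stroke recurrence (replaces the state utility)
  u_recurrence: {value: 0.42, low: 0.11, high: 0.71}
  # one-cycle utility decrement for symptomatic intracranial hemorrhage
  sich_disutility: {value: 0.38, low: 0.30, high: 0.46}
costs:
  # 1.614 CNY/mg is the national centralized-procurement median; the one-way
  # range 1.58-7.05 spans the first to third procurement quartiles and 25.5
  # is the highest listed market price (scenario analysis)
  drug_price_per_mg: {value: 1.614, low: 1.58, high: 7.05}
  drug_price_max: 25.5
  acute_mrs01: {value: 12472, low: 7204, high: 15704}
  acute_mrs25: {value: 16490, low: 9063, high: 21624}
  acute_death: {value: 14133, low: 6640, high: 18679}
  sich_cost: {value: 3012, low: 654, high: 6285}
  annual_post_mrs01: {value: 8867, low: 2655, high: 11311}
  annual_post_mrs25: {value: 13492, low: 3393, high: 16968}
  recurrent_stroke_cost: {value: 18380, low: 13785, high: 22976}
  infusion_first_hour: {value: 15.6, low: 5.0, high: 30.0}
  infusion_additional_hour: {value: 1.0, low: 0.5, high: 2.0}
settings:
  discount_rate: {value: 0.05, low: 0.0, high: 0.08}
  start_age: 66
  horizon_years: 30
  cycle_length: 0.25
  wtp_1x: 89358
  wtp_3x: 268074
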