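label: Taiwan base case
currency: 2020 US$
comparator: standard_care
intervention: dapagliflozin
settings:
  horizon_cycles: 180
  annual_discount: 0.03
  start_age: 66.0
  cohort_size: 1000.0
arms:
  standard_care:
    transitions:
      p_hhf: 0.007881397
      p_cv_death: 0.006698743
      p_noncv_death: 0.001312441
    drug_monthly: 0.0
  dapagliflozin:
    transitions:
      p_hhf: 0.005611395
      p_cv_death: 0.005509456
      p_noncv_death: 0.001138597341033
    drug_monthly: 28.600000000000001
costs:
  stable_monthly: 450.0
  event_month: 2887.0
  death_month_cv: 3430.0
  death_month_noncv: 3390.0
utilities:
  stable_hf: 0.77
  aging_decrement_per_year: 0.0016
  hhf_decrement: 0.321
distributions:
  standard_care.p_hhf:
    family: beta
    mean: 0.007881397
    sd: 0.001816007
  standard_care.p_cv_death:
    family: beta
    mean: 0.006698743
    sd: 0.001675218
  standard_care.p_noncv_death:
    family: beta
    mean: 0.001312441
    sd: 0.000743514
  dapagliflozin.p_hhf:
    family: beta
    mean: 0.005611395
    sd: 0.001533432
  dapagliflozin.p_cv_death:
    family: beta
    mean: 0.005509456
    sd: 0.001519518
  dapagliflozin.p_noncv_death:
    family: beta
    mean: 0.001138597341033
    sd: 0.000314027220555
  dapagliflozin.drug_monthly:
    family: gamma
    mean: 28.600000000000001
    sd: 14.300000000000001
  stable_monthly:
    family: gamma
    mean: 450.0
    sd: 225.0
  event_month:
    family: gamma
    mean: 2887.0
    sd: 1443.5
  death_month_cv:
    family: gamma
    mean: 3430.0
    sd: 1715.0
  death_month_noncv:
    family: gamma
    mean: 3390.0
    sd: 1695.0
  utility_stable:
    family: beta
    mean: 0.77
    sd: 0.016
  utility_aging_decrement:
    family: beta
    mean: 0.0016
    sd: 0.0001
  utility_hhf_decrement:
    family: beta
    mean: 0.321
    sd: 0.02
wtp:
  very_cost_effective: 25000.0
  cost_effective: 75000.0
notes: dapagliflozin p_noncv_death reconciled to the arm's 69.9% 15-year mortality
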