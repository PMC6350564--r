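# Base-case inputs for the OPEP-vs-no-PEP COPD cost-utility model.
# Costs are 2017 Canadian dollars; probabilities are per monthly cycle
# unless flagged otherwise.
currency: CAD2017
params:
  p_exac_month1: 0.257      # moderate-to-severe exacerbation, cycle 1
  p_exac_later: 0.059       # same hazard, cycles 2-12
  rr_month1: 0.72           # device relative risk, cycle 1
  rr_later: 1.0             # device relative risk, cycles 2-12 (base case)
  frac_severe_device: 0.691 # severe share of exacerbations, device arm
  frac_severe_control: 0.706
  p_death_severe: 0.110     # case fatality of a severe exacerbation month
  p_death_annual: 0.010     # background COPD mortality, per YEAR
  cost_severe: 13119        # per severe exacerbation month
  cost_moderate: 456        # per moderate exacerbation month
  cost_no_exac: 65          # outpatient follow-up, per month (printed value)
  cost_device: 90           # device acquisition, per patient per year
  utility_copd: 0.897       # baseline utility, per year (printed value)
  decrement_severe: 0.504   # utility decrement per severe month
  decrement_moderate: 0.12  # utility decrement per moderate month
  n_cycles: 12
# Raw ingredients of the composite inputs above; used to re-derive
# utility_copd, cost_no_exac and the decrements when those keys are absent.
derivation:
  severity_weights: [0.27, 0.55, 0.15, 0.03]      # mild/moderate/severe/very severe
  severity_utilities: [0.97, 0.93, 0.72, 0.52]
  outpatient_unit_costs: [78, 251, 101]           # physician / antibiotics / corticosteroids
  outpatient_frequencies: [0.131, 0.172, 0.113]   # uses per patient-month
  annual_decrements:
    severe: 0.042
    moderate: 0.01
# Sampling family per parameter for probabilistic sensitivity analysis.
distributions:
  p_exac_month1: beta
  p_exac_later: beta
  p_death_severe: beta
  p_death_annual: beta
  rr_month1: lognormal
  rr_later: lognormal
  frac_severe_device: beta
  frac_severe_control: beta
  cost_severe: gamma
  cost_moderate: gamma
  cost_no_exac: gamma
  utility_copd: beta
  decrement_severe: gamma
  decrement_moderate: gamma
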