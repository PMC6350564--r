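# opepcua

Cost-utility analysis of oscillating positive expiratory pressure (OPEP)
airway clearance in post-exacerbation COPD, as a reusable, tested R
package.

## The problem

Patients recovering from a COPD exacerbation face a high risk of
re-exacerbation: a moderate event sends them to the emergency room, a
severe one puts them in hospital (where roughly one in ten die), and both
are costly and sharply reduce quality of life. Hand-held OPEP devices
mobilise airway mucus and have been shown to reduce re-exacerbations in
the month after use begins. The question for a payer: does giving every
post-exacerbation patient a ~$90 device save money and health over the
following year?

`opepcua` answers this with a four-state Markov cohort model (monthly
cycles, one-year horizon, no discounting): states *no exacerbation*,
*moderate exacerbation*, *severe exacerbation*, and *dead* (absorbing).
All patients enter exacerbation-free; each month they may exacerbate
(first-month hazard `p₁ = 0.257`, thereafter `p = 0.059`, multiplied in
the device arm by a relative risk `RR₁ = 0.72` in month 1 and `RR = 1`
after), die, or stay event-free. Each state-month accrues a cost
(severe $13,119, moderate $456, none $65, in 2017 CAD) and a utility
contribution `u/12 − d`, where `u = 0.897` is the baseline COPD utility
and `d` is the event decrement (severe 0.504, moderate 0.12 per month —
a severe month is worse than dead). Strategies are compared by
incremental cost `ΔC`, incremental QALYs `ΔE`, and either the ICER
`ΔC/ΔE` or a dominance verdict; uncertainty is handled by one-way ±20%
sensitivity analysis (tornado) and by 100,000-draw probabilistic
sensitivity analysis with beta (probabilities, shares, utility), gamma
(costs, decrements) and log-normal (relative risks) distributions fitted
by the method of moments, treating ±20% as a 95% interval
(`SD = mean × 0.20 / 1.96`). Cost-effectiveness at a willingness to pay
λ is positive net monetary benefit `ΔE·λ − ΔC > 0`.

For the audience: health economists and HTA analysts who want to
reproduce, stress or adapt this evaluation, and methodologists who want
a compact, fully validated cohort model with an explicit account of its
accounting conventions (survivor routing, half-cycle correction,
decedent accrual — see `?convention_config` and the methods vignette).

## Worked example

```r
library(opepcua)

params <- model_params()          # published Canadian base-case inputs
evaluate_strategy_pair(params)
#> Incremental cost-utility result (device vs control)
#>   cost:  device $7974.90, control $8664.89, incremental $-689.98
#>   QALYs: device 0.5649, control 0.5289, incremental 0.0360
#>   classification: dominant
```

The device arm costs $690 less and gains 0.036 QALYs per patient over
the year, so the device *dominates* usual care: no ICER is reported
because the device is both cheaper and more effective. If the one-month
effect persists all year (`run_scenario(params)`), the saving grows to
$2,186.31 and the gain to 0.104 QALYs.

```r
psa <- run_psa(params, n_draws = 100000, seed = 1)
psa
#> Probabilistic sensitivity analysis (100000 draws, seed 1)
#>   mean incremental cost:  $-692.11
#>   mean incremental QALYs: 0.0361
#>   cost-effectiveness plane regions:
#>     dominant         72.8%
#>     ne_below_wtp      4.9%
#>     ne_above_wtp      2.4%
#>     dominated        19.9%
#>     sw                0.1%
#>   P(cost-effective at $50,000/QALY): 77.7% (NMB), 77.7% (regions)
```

Under joint parameter uncertainty the device is dominant in ~73% of
draws and cost-effective at $50,000/QALY in ~78%; because exacerbations
drive both costs and utility losses, draws are mostly either dominant
(device prevents events) or dominated (it does not), with little in
between. The tornado (`one_way_dsa(params)`) is led by the severe share
of exacerbations in the untreated arm, whose ±20% range swings the
incremental cost from +$784 to −$2,147.

Model inputs live in one editable YAML document
(`inst/extdata/copd_base_case.yaml`); `load_params()` validates it and
re-derives the composite inputs (severity-weighted utility, outpatient
cost, monthly decrements) when they are omitted. Every stage also runs
on random valid inputs from `generate_random_param_set()`, and
`microsimulate_arm()` provides an independent patient-level oracle for
the cohort engine.

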