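---
title: "Methods: a Markov cohort cost-utility model of OPEP therapy in COPD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-utility model of OPEP therapy in COPD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opepcua)
```

## The model

The package implements a discrete-time cohort model of the year after a
COPD exacerbation, comparing two strategies that differ only in whether
the patient uses an oscillating positive expiratory pressure (OPEP)
device. Four health states: *no exacerbation*, *moderate exacerbation*
(an emergency visit without admission), *severe exacerbation* (a
hospital admission), and *dead*, which is absorbing. Cycles are months;
the horizon is 12 cycles; nothing is discounted over a single year.

Every patient enters exacerbation-free. In each cycle a patient in the
exacerbation-free state exacerbates with hazard $p_m$ — $p_1 = 0.257$ in
the first month after the index exacerbation, $p_m = 0.059$ thereafter —
multiplied in the device arm by a relative risk ($RR_1 = 0.72$ in cycle
1; $RR = 1$ afterwards in the base case). An exacerbation is severe
with probability $s$ (0.691 device / 0.706 control) and moderate
otherwise. A severe exacerbation month ends in death with probability
0.110 (an in-hospital case fatality); all other alive states face the
background COPD mortality of 0.010 *per year*, converted to a monthly
probability. Exacerbation states last exactly one cycle: survivors
return to the exacerbation-free process.

Rewards are attached to state-months. Costs (2017 CAD): $13,119 for a
severe month, $456 for a moderate month, $65 for an exacerbation-free
month, plus the $90 annual device cost in the device arm. Utility: an
alive month contributes $u/12 - d$ QALYs, with baseline utility
$u = 0.897$ and decrements $d$ of 0.504 (severe) or 0.12 (moderate) per
event-month; a severe month's contribution, $0.897/12 - 0.504 =
-0.429$, is deliberately negative — a hospitalised exacerbation month is
valued below dead. Strategies are compared by incremental cost and
QALYs; if the device is cheaper and more effective it *dominates* and no
ICER is reported.

### Composite inputs

Three inputs are themselves aggregates, and the package carries their
derivations so a user can start from the raw ingredients
(`derivation` block of the YAML document):

* baseline utility $u = \sum_k w_k u_k$ over the severity distribution
  of the COPD population (weights 0.27/0.55/0.15/0.03 for
  mild/moderate/severe/very severe, utilities 0.97/0.93/0.72/0.52),
  giving 0.897 exactly;
* the exacerbation-free monthly cost as utilisation-weighted outpatient
  unit costs, $78 \cdot 0.131 + 251 \cdot 0.172 + 101 \cdot 0.113 =
  64.80$, carried in the base case at its printed rounding of \$65;
* monthly event decrements as $12\times$ the annual decrements 0.042 and
  0.01.

The base case uses the *printed* composite values rather than re-derived
unrounded ones; the derivation functions exist for validation and for
users supplying their own ingredients.

## Accounting conventions and their calibration

Cohort models of this size hide several accounting choices that the
usual prose description leaves open. The package makes each one an
explicit switch (`convention_config()`):

* **Survivor routing.** After an exacerbation month, does the survivor
  spend the next month unconditionally exacerbation-free (`"simple"`,
  a strict one-cycle tunnel), or re-enter the exacerbation-free risk
  process immediately, so back-to-back exacerbations can occur
  (`"composite"`)?
* **Death competition.** Is background mortality applied to the
  non-exacerbating remainder (`"after_exac"`) or split off first
  (`"before_exac"`)? At a monthly background mortality of ~0.0008 the
  difference is a few dollars.
* **Reward timing.** Count the cohort at the end of each cycle, or
  half-cycle correct (trapezoid of entering and exiting occupancy)?
* **Device cost timing.** Charge the \$90 once at entry to every
  device-arm member, or prorate it monthly over survivors.
* **Decedent accrual.** A patient who dies out of an exacerbation month
  accrues that month's full cost and (negative) utility (`"full"`), on
  the argument that hospital costs are incurred before death, or
  accrues nothing (`"none"`).
* **Annual-to-monthly conversion.** Constant hazard
  $1-(1-p)^{1/12}$ or the naive $p/12$; they differ by $<10^{-5}$ at
  $p = 0.01$, so this switch exists for transparency, not effect.

The published totals were produced with commercial decision-tree
software whose conventions are not stated, so we calibrated: the
deterministic results were evaluated under every combination of
survivor routing, death competition and reward timing (twelve
configurations, well under a second each) and compared with the
published per-arm totals. Exactly one configuration reproduces all of
them within tight bands — **composite survivor routing, death competing
after the exacerbation split, half-cycle correction on, device cost at
entry, full decedent accrual** — and it is therefore the package
default:

```{r base-case}
evaluate_strategy_pair(model_params())
```

against published totals of \$8,835.71 / \$8,141.56, QALYs 0.53 / 0.57,
and an incremental \$-694.15 / +0.04 QALYs (all matched within 2% /
0.005–0.018 QALYs). The simple-tunnel, end-of-cycle alternative
undershoots the control-arm cost by ~3.4%, which is what identifies the
composite reading: with a 25.7% first-month hazard, excluding
back-to-back exacerbations discards too much cost. The sustained-effect
scenario (`run_scenario()`: $RR = 0.72$ all year) reproduces the
published \$2,123.52 saving within \$63 and the 0.10 QALY gain within
0.004 under the same configuration, as do the probabilistic proportions
below. Every convention switch remains available for users who want the
model under different accounting.

## Sensitivity analyses

**One-way (tornado).** Every input with a published plausible range —
fourteen: four event probabilities, two relative risks, two severity
shares, three state costs, the baseline utility, two decrements; the
device cost carries no range — is varied to mean ∓/± 20% with all others
at base case. Bounds of probabilities, shares and the utility are
truncated to $[0,1]$ (the utility's upper bound, $0.897 \times 1.2 =
1.076$, truncates to 1). Varying a severe share moves the moderate share
to its complement automatically, because moderate events are modelled as
the non-severe remainder — shares stay on the simplex by construction.
Rows are ranked by the width of the incremental-cost range. The leading
variable is the control-arm severe share, spanning roughly $-\$2{,}150$
to $+\$780$ around the base-case $-\$690$.

**Probabilistic.** All fourteen parameters are drawn independently each
trial: beta for probabilities, shares and the utility; gamma for costs
and decrements; log-normal for relative risks (the later-cycle relative
risk is sampled log-normally around 1). Each distribution is fitted by
the method of moments to the base-case mean and to
$SD = \text{mean} \times 0.20 / 1.96$, i.e. the ±20% range read as a
95% interval. This SD rule is applied generically to every sampled
parameter — that is how the published ranges are constructed — and the
chosen families respect each parameter's support, so no draw needs
clipping. Both arms are evaluated on the same drawn set within a trial;
100,000 trials by default, fully vectorised (a 100,000-draw run takes
about a second). The plane regions partition draws into dominant /
dominated / north-east on either side of the willingness-to-pay line /
south-west; cost-effectiveness at λ is defined by positive net monetary
benefit, and the additive region count (dominant + NE-below-line) is
reported alongside since the two differ only by the ~0.1% south-west
share. With seed 1 the run gives ~72.8% dominant, ~19.9% dominated and
~77.7% cost-effective at \$50,000/QALY, against published values of
72.2%, 20.8% and 76.8%.

## Validation design

Two independent routes guard the engine:

* a hand-built transition-row constructor in the test helpers, written
  entry by entry from the model description, checked against the
  engine's rows across random parameter sets, states, cycles and all
  convention switches;
* a patient-level microsimulation (`microsimulate_arm()`) that samples
  individual paths with the engine's rows and applies the reward rules
  per patient; cohort totals must sit within Monte-Carlo error of its
  means. The base-case comparison uses 40,000 patients against a strict
  3-SE band. The property sweep runs 100 random parameter sets at 3,000
  patients each (200 comparisons, alternating arms and routings); there
  the per-comparison bound is the family-wise 3σ value (Bonferroni,
  ≈3.9 SE), and the mean squared z-score must lie in $[0.5, 1.5]$ — a
  literal 3-SE rule on 200 comparisons would fail a correct
  implementation about 40% of the time by multiplicity alone, while the
  aggregate check is far more sensitive to systematic bias.

The vectorised accrual used by the probabilistic analysis is also
checked draw-by-draw against the scalar cohort run, so the PSA and the
base case cannot drift apart.

## The synthetic parameter generator

`generate_random_param_set()` draws internally valid input tables far
from the published ones: hazards uniform on $(0, 0.5)$, severe shares on
$(0.3, 0.9)$, case fatality on $(0, 0.3)$, background annual mortality
on $(0, 0.05)$, ordered positive costs (severe > moderate >
exacerbation-free, spanning two orders of magnitude), utility on
$(0.5, 1)$, ordered decrements, relative risks spanning protective to
harmful. These ranges are wide enough to exercise regimes the base case
never reaches (high mortality, weak cost separation, harmful devices)
while guaranteeing every validation invariant. What passing on such
inputs shows is *internal* consistency — conservation, monotone death,
correct accounting, cohort/microsimulation agreement; it does not show
that the published inputs are right for any real population, nor that
exacerbation risks are truly memoryless month to month.

## Numerical choices

Occupancy conservation is enforced to $10^{-12}$ by constructing each
row's stay-probability as one minus the other entries. Hazard × relative
risk products are capped at 1 (unreachable at base-case values, possible
in principle under extreme log-normal draws). A zero QALY difference
makes the ICER undefined: the comparison is labelled by the cost sign
with an explicit `icer_defined = FALSE` flag rather than reporting an
infinite ratio. Beta fitting requires $s^2 < m(1-m)$ and errors
otherwise rather than truncating. Serialisation writes doubles at 17
significant digits so a parameter document round-trips bit-identically.
Test problem sizes — 40,000-patient base-case oracle runs, 3,000-patient
sweep runs, $10^6$-draw moment-recovery checks, 100,000-draw
probabilistic runs — were chosen so the full suite completes in well
under a minute while keeping Monte-Carlo error far below every tolerance
tested.

## Limitations

The model inherits the published evaluation's scope: a single year, no
discounting, no treatment discontinuation or adherence decay (the base
case instead zeroes the device effect after month 1), no age- or
severity-dependent background mortality, one exacerbation at most per
month, and effectiveness imported from a 30-day observational study.
Parameters are sampled independently in the probabilistic analysis —
correlations (e.g. between the two severity shares) are not modelled
because no joint information is published. Costs are Alberta 2017
values; transferring them requires re-pricing, for which
`load_params()` accepts any valid document.
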