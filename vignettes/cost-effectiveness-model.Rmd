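---
title: "A Markov cohort model for add-on dapagliflozin in HFrEF: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for add-on dapagliflozin in HFrEF: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfcea)
```

## The decision problem

Dapagliflozin, an SGLT-2 inhibitor, reduces hospitalization for heart
failure (HHF) and cardiovascular (CV) death when added to standard care in
heart failure with reduced ejection fraction (HFrEF). Whether a payer
should reimburse it depends on whether the health gained per dollar spent
clears the system's willingness to pay (WTP). `hfcea` implements the full
modelling chain for that question: a discrete-time Markov cohort model of
disease progression, cost and quality-adjusted life-year (QALY)
accumulation, incremental cost-effectiveness ratios (ICERs) against tiered
WTP thresholds, deterministic and probabilistic sensitivity analysis, a
scenario/battery runner, and a claims-based procedure for estimating the
cost inputs from longitudinal claims data, validated end to end on a
synthetic claims generator with known ground truth.

## Model structure and assumptions

The state space has four states: **stable HF** (entry state, also covering
post-HHF months), an **acute HF event** state (emergency visit or HHF), and
two absorbing death states (**CV death**, **non-CV death**). Cycles are one
month; the base-case horizon is 180 cycles (15 years) for a cohort entering
at age 66. The acute-event state is a one-cycle tunnel returning to stable
HF: the published state diagram merges "stable HF or post-HHF" into one
state, and no separate post-event monthly cost is listed among the inputs,
so post-event months accrue stable-state costs. Both alive states carry the
same per-arm transition probabilities (one set per arm is published);
an acute-to-acute transition counts as a new event.

Monthly transition probabilities come from the DAPA-HF trial via the
standard constant-hazard conversion, `r = -ln(1 - p) / t` and
`p = 1 - exp(-r t)` (implemented in `prob_to_rate()`, `rate_to_prob()`,
`rescale_prob()`). Probabilities of exactly 1 are rejected rather than
mapped to an infinite rate; the model never needs certain events. The
canonical internal time unit is months, the model cycle; probabilities on
other horizons are rescaled on ingestion. Hazards are constant over the
horizon — no age dependence — matching the source analysis, which treats
this as a limitation and probes it through the 18-month horizon scenario.

### The inconsistent non-CV death input

The published input table prints the dapagliflozin non-CV death probability
identical to its CV death probability (0.005509456). That cannot be right:
it implies a combined monthly death probability of 0.011, i.e. 86%
15-year mortality, whereas the results report 69.9% for that arm. The
default configuration (`taiwan_base_config()`) therefore *reconciles* the
value: the arm's total monthly death probability solves
`(1 - p_total)^180 = 1 - 0.699`, and the non-CV component is `p_total`
minus the printed CV value, about 0.0011386 — close to the comparator's
0.0013124, as expected for a cause of death the drug does not influence.
The printed value remains available via
`taiwan_base_config(reconcile_noncv = FALSE)`. The sampling standard
deviation attached to the reconciled value preserves the printed row's
*relative* uncertainty (27.6% of the mean, giving sd ≈ 0.00031): carrying
the printed absolute SD (0.00152) onto a mean of 0.00114 would assert 133%
relative uncertainty, which is implausible on its face and degenerate for
both beta sampling and one-way bounds.

A related, deeper inconsistency: the published life-year and QALY totals
(e.g. 13.46 LYs for standard care) are not attainable under any constant
monthly hazard that also produces the published 76.5% mortality — 0.00801
per month gives roughly 7.9 undiscounted life-years over 180 cycles. The
event counts (753 and 590 per 1000 patients) and mortality fractions *are*
mutually consistent with the monthly inputs, and those are the quantities
this package anchors its end-to-end checks on. Absolute cost/QALY totals
and hence the exact ICER value are reproduced in structure but not to the
printed digit (the engine gives ≈ US$11,000/QALY against the published
12,035); both sit far below the US$25,000 threshold that carries the
published conclusion.

## Costing and utility rules

Per cycle, with occupancy taken after the cycle's transition:

* every alive month accrues the stable-HF monthly cost plus the arm's drug
  cost (US$28.6/month for dapagliflozin; standard care's own drug costs are
  inside the stable-state cost);
* months in the acute-event state additionally accrue the event-month cost
  (US$2887);
* the cycle of a death transition accrues, once, the cost of the month
  before death (US$3430 CV, US$3390 non-CV);
* utility in an alive month is 0.77 minus an aging decrement of 0.0016 per
  year since model entry (applied linearly, measured at the cycle's start),
  minus 0.321 in acute-event months; each month contributes utility/12
  QALYs and 1/12 life-years. Decrements are stored as magnitudes and
  subtracted; utilities that would fall below zero are floored at zero with
  a warning (never reached by the shipped inputs).

Costs and QALYs are discounted at `(1 + d)^(-t/12)` with `d = 0.03` per
year and `t` the 1-based cycle index; life-years are reported both
discounted and undiscounted. There is **no half-cycle correction** — the
source describes none — which makes every number bit-for-bit reproducible
from the rules above. All monetary fields are 2020 US$.

## Incremental analysis

`icer()` forms increments from unrounded totals and only the report layer
rounds; the published table itself shows why this matters (its abstract and
table disagree by rounding, 12,305 vs 12,035). Dominance follows the
standard quadrant convention: cheaper-and-more-effective is *dominant*,
costlier-and-no-more-effective is *dominated*; ratios are only formed
otherwise. Decisions use the two-tier thresholds of roughly one and three
times GDP per capita (US$25,000 / US$75,000 per QALY for Taiwan):
ICER at or below the lower tier is "very cost-effective", at or below the
upper "cost-effective". Net monetary benefit `NMB = λ·ΔQALY − ΔC` backs
the probabilistic decision rule.

## Sensitivity analysis

**One-way (tornado).** The source never states its bound convention, so
bounds are configuration-first with defaults of mean ± 1 SD for
probabilities and utilities (truncated to valid ranges) and mean ± the
printed half-range for costs (the half-range equals the SD in every row, so
all cost distributions are shape-4 gammas). Exact published bar lengths are
therefore not reproducible — only the ordering is meaningful, and the
engine reproduces it: the two arms' CV-death probabilities dominate the
ICER. A bound that pushes the model into dominance has no finite ICER; its
span is recorded as infinite, which is the honest reading of "the ICER is
unboundedly sensitive here".

**Probabilistic.** Each of the 10,000 iterations samples every parameter
from its distribution — beta via method of moments for probabilities and
utilities (decrements sampled on their magnitude), gamma for costs — runs
both arms, and records the incremental pair. Draws whose monthly
probabilities sum past 1 in either arm are resampled, not clipped, keeping
marginals unbiased (the count is reported; it is zero under the shipped
inputs). The cost-effectiveness probability at λ is the exact empirical
fraction of draws with positive NMB, and `ceac()` traces it over a λ grid.

The one genuinely open design question is the *joint* distribution of the
two arms' transition probabilities, which the source does not state. Two
readings:

* *independent* — each arm's beta sampled on its own. Because the two
  CV-death distributions overlap substantially, about 30% of draws reverse
  the treatment effect, and the CE probability at US$25,000 collapses to
  roughly 0.67–0.71.
* *paired* (the default) — each transition probability pair is sampled at a
  shared quantile of the two arms' marginals (comonotone coupling). Every
  marginal stays exactly as published; what is shared is the baseline-risk
  uncertainty, while the relative treatment effect stays near its trial
  estimate. This is the reading consistent with inputs that come from one
  randomized comparison: the trial established the effect *direction* with
  high confidence (CV death HR 0.82, 95% CI 0.69–0.98), and independent
  sampling would re-litigate it in nearly a third of draws.

The paired reading reproduces the published probabilistic results in
structure and magnitude: CE probability ≈ 0.99 at US$25,000 (published
99.3%), collapsing to ≈ 0.33 when the CV-death risks are forced equal
(published 33.0%) and to ≈ 0.49 on the 18-month horizon (published 43.8%).
Under the independent reading those published numbers are unreachable —
which is the empirical ground for making paired the default.
`run_psa(..., sampling = "independent")` keeps the alternative one keyword
away. No user-specified correlation structure beyond this pairing is
supported. Parameters not paired across arms (costs, utilities, drug cost)
are always mutually independent.

## Scenarios, subgroups, countries

`apply_scenario()` applies declarative overrides — horizon (18 months / 30
years), discount rate (0% / 10%), equal-risk flags that copy a comparator
transition into the intervention arm (no treatment effect on that risk),
and drug-price multipliers (25/50/75%) — returning a new validated
configuration with provenance recorded; the base is never mutated. The
`"emergency"` equal-risk flag is an alias of `"hhf"`: this state space
merges emergency visits and HHF into one acute state with a single
published probability per arm (the source's separate scenario rows used
pre-merge trial inputs that are not published). The 18-month scenario keeps
the same per-cycle discounting rule over the shorter horizon; setting the
discount override to 0 disables it. Subgroup analyses are alternative
transition-input sets supplied through configuration — the machinery runs
them, but the subgroup input values live in unavailable supplementary
material and are not bundled. Country profiles ship the 2020
one-GDP-per-capita WTP thresholds only (Japan 39,000; Korea 30,000;
Singapore 58,000; Australia 52,000; Taiwan 25,000); country cost/utility
sets are user-supplied for the same reason, so the published
country-specific ICERs are out of scope.

## Claims-based cost estimation

The costing procedure mirrors how the original inputs were built from
national claims data. Patients enter the stable-HF cohort with at least two
ambulatory HF-flagged claims within 180 days inside the index year and no
HF emergency visit or admission in the 180 days before the first index-year
diagnosis; attrition is reported per filter. Stable monthly cost is each
patient's summed costs from index until the first acute HF event, the
month before death, or the administrative censor date, divided by follow-up
in 30-day months, averaged over the cohort. The first 30 days from an acute
episode's start form the event month; subsequent complete 30-day windows
(up to the month before death or censoring) are state months. Death-month
costs are the cause-specific means of costs in the 30 days up to death.

Design choices where the source is silent: months are **30-day windows
anchored** at the patient's own index/episode/death dates (calendar months
would make window lengths depend on the calendar and dates non-uniform);
stable follow-up ends 30 days *before* death so the death month is never
pooled into stable costs — with anchored windows this makes the four pools
provably disjoint, and a conservation test verifies that on toy data the
pools sum exactly to total claimed cost. Claims ingest from CSV with a
documented schema; diagnosis coding is a boolean HF flag (a mapping layer
from code lists such as ICD-9-CM 428 is the caller's concern), and CPI
adjustment to reference-year prices is a per-year scalar table applied
multiplicatively before estimation.

## The synthetic claims generator

`generate_claims()` exists so the whole chain is testable without any
restricted data. Each synthetic patient indexes on a random day in the
first half of the index year, emits one ambulatory claim per 30-day month
with gamma-distributed cost, and from the second month on faces a single
categorical draw per month competing the acute-event hazard against the two
death hazards — exactly the structure of the cohort model's transition row.
An event opens an inpatient episode with an event-month cost, followed by
state-months at their own cost level; death months carry only the
cause-specific death claim. Partial trailing months at the censor date are
prorated so per-month cost means stay unbiased. Fractions of patients are
constructed to fail each cohort filter, exercising the attrition
accounting. Defaults mirror the published base-case inputs (stable cost
450 ± 225, event month 2887 ± 1443.5, death months 3430 ± 1715 and
3390 ± 1695, hazards 0.0078814 / 0.0066987 / 0.0013124); the state-month
cost, which the published inputs never print (the one-cycle tunnel does not
use it), defaults to 700 ± 350 as a modest post-discharge elevation over
the stable level.

What the generator does **not** emulate: realistic diagnosis-code
distributions, comorbidity and utilization structure, fee schedules,
seasonal or calendar effects, or informative censoring. Parameter-recovery
tests passing on this generator therefore show the estimators implement
their definitions correctly — not that those definitions are robust to the
messiness of real claims.

## Numerical and testing choices

* The deterministic trace is plain matrix propagation; occupancy is
  conserved to 1e-10 per cycle and death occupancy is monotone.
* `microsimulate_cohort()` is the engine's independent stochastic oracle:
  100,000 individually simulated patients agree with the cohort trace
  within 3 Monte Carlo SE on mortality (binomial SE) and event counts
  (using the conservative per-person variance bound Var ≤ 2·E, measured
  ≈ 0.92 against the bound's 1.5 for the base-case inputs).
* Probability/rate round-trips hold to 1e-12 relative error over
  p ∈ (0, 0.999].
* All randomness (microsimulation, PSA, claims generation) flows through
  explicit integer seeds; identical seed and inputs give identical output,
  and seeded helpers restore the caller's RNG state.
* Test problem sizes: PSA checks run 10,000 iterations, parameter
  recovery uses 2,000 synthetic patients, the microsimulation oracle
  100,000 individuals — sizes at which the Monte Carlo tolerances above
  are discriminating while the whole suite stays fast.

## Known limitations

Constant hazards (no aging of risks); two strategies only (no efficiency
frontier over more arms); no half-cycle correction; no renal or other
organ-system states; no expected-value-of-perfect-information analysis; the
PSA's paired sampling is a structural assumption, not an estimated
correlation; absolute cost/QALY totals inherit the source's internal
inconsistency discussed above and should be read as model-consistent
values, not replications of the printed table.
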