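# hfcea

Cost-effectiveness modelling of add-on dapagliflozin versus standard care
for heart failure with reduced ejection fraction (HFrEF), from a healthcare
payer's perspective. The package is aimed at health-economic analysts who
want a fully scripted, testable version of this analysis: a Markov cohort
engine, incremental cost-effectiveness measures, deterministic and
probabilistic sensitivity analysis, a scenario runner, and a claims-based
cost-estimation procedure validated against a synthetic claims generator
with known ground truth.

## The model

A discrete-time Markov cohort model with monthly cycles tracks a cohort
entering **stable HF** at age 66 over a 15-year horizon (180 cycles). Each
month, alive patients face an acute HF event (emergency visit or
hospitalization for HF, a one-cycle tunnel state) with probability
*p*<sub>HHF</sub>, cardiovascular death with *p*<sub>CV</sub>, and
non-cardiovascular death with *p*<sub>nCV</sub>; the remainder returns to
stable HF. Probabilities move between horizons by the constant-hazard
transform *r* = −ln(1 − *p*)/*t*, *p* = 1 − e<sup>−*rt*</sup>.

Each cycle accrues costs (stable care + drug, plus event-month and
death-month costs on the corresponding transitions) and utilities
(0.77 baseline, minus aging and event decrements), discounted at
(1 + 0.03)<sup>−*t*/12</sup>. Two strategy arms are compared by

ICER = (C<sub>dapa</sub> − C<sub>soc</sub>) / (E<sub>dapa</sub> − E<sub>soc</sub>) [US$ per QALY]

against willingness-to-pay tiers of US$25,000 and US$75,000 per QALY
(about 1x and 3x Taiwan's 2020 GDP per capita). The probabilistic
sensitivity analysis samples all inputs (beta for probabilities and
utilities, gamma for costs) and reports the probability of positive net
monetary benefit λ·ΔQALY − ΔC.

## Worked example

```r
library(hfcea)

res <- run_model(taiwan_base_config())
print(res)
```

```
<model_result: Taiwan base case>
<arm_outcome: standard_care>
  cost  (disc.)      40243.19 US$
  QALY  (disc.)        5.0854
  LY  (undisc.)        7.8930
  expected HHF          752.5 events (cohort 1000)
  mortality              76.5 %
<arm_outcome: dapagliflozin>
  cost  (disc.)      45532.51 US$
  QALY  (disc.)        5.5646
  LY  (undisc.)        8.7037
  expected HHF          590.0 events (cohort 1000)
  mortality              69.9 %
<incremental_result: dapagliflozin vs standard_care>
  delta cost       5289.32 US$
  delta QALY        0.4792
  delta LY          0.8107
  ICER/QALY        11038.1
  ICER/LY           6524.5
  decision: very cost-effective
```

Per 1000 patients over 15 years, standard care accrues 753 expected
hospitalizations for HF and 76.5% cumulative mortality; adding
dapagliflozin cuts these to 590 events and 69.9%, at an incremental
discounted cost of about US$5,289 for 0.479 extra QALYs — roughly
US$11,000 per QALY gained, far below the US$25,000 "very cost-effective"
tier. Sensitivity analysis:

```r
psa <- run_psa(taiwan_base_config(), iterations = 10000, seed = 1)
print(psa)
#> <psa_result: 10000 iterations, seed 1, 0 resampled>
#>   P(cost-effective | WTP 25000 US$/QALY) = 0.989
#>   P(cost-effective | WTP 75000 US$/QALY) = 1.000

head(one_way_dsa(taiwan_base_config())$parameter, 2)
#> [1] "standard_care.p_cv_death" "dapagliflozin.p_cv_death"
```

The tornado confirms the two arms' cardiovascular mortality inputs as the
dominant drivers of the ICER.

The `analysis/` directory holds the narrative drivers — `01_base_case.R`,
`02_sensitivity.R` (tornado, PSA, CEAC, country thresholds),
`03_scenarios.R` (horizon, discounting, equal-risk, drug-price scenarios),
`04_claims_costing.R` (synthetic-claims cost estimation with
parameter-recovery table) — each writing CSV tables under `results/`.
One published input is reconciled before use: see `?taiwan_base_config`
and the methods vignette (`vignettes/cost-effectiveness-model.Rmd`) for
why and how.

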