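# strokeCEA

Cost-effectiveness modelling of intravenous argatroban added to standard
antiplatelet therapy for acute ischemic stroke (AIS) with early neurological
deterioration (END), from the perspective of the Chinese healthcare system.
The package is written for health economists and methodologists who want a
fully scripted, testable re-implementation of this decision model: every
input is a published summary value, every analysis is a function call, and
every published figure of merit can be recomputed from scratch.

## The model

A 3-month **decision tree** assigns each arm its modified Rankin Scale (mRS
0–6) distribution at month 3: the control arm uses the trial's control
distribution *p*, the argatroban arm uses the risk-ratio-weighted
distribution

```
p_i' = p_i RR_i / Σ_j p_j RR_j ,    i = 0, …, 6
```

together with arm-specific symptomatic intracranial hemorrhage (sICH)
probabilities, acute-care costs by outcome severity, and the drug course
(60 mg/day × 2 d + 20 mg/day × 5 d = 220 mg, plus continuous-infusion fees).

The month-3 distribution then seeds a **Markov cohort model** with seven
states (mRS 0–5 and dead) run in quarterly cycles over a 30-year horizon
(119 cycles after the tree). Each cycle, a patient in alive state *j* may
(at most one event per cycle):

* suffer a recurrent stroke, with per-cycle probability
  `p = 1 − exp(log(1 − R)/4)` converted from the annual incidence
  `R = 0.112`; recurrence is fatal with probability 0.21, and survivors are
  redistributed uniformly over states `j..5` (no improvement after
  recurrence);
* die of non-stroke causes, with the age-band background mortality converted
  to a quarterly rate and multiplied by the state-specific death hazard
  ratio (1–2.37);
* otherwise remain in state *j*.

Costs (2023 CNY: acute care, annual post-hospitalization care by severity,
recurrence events, sICH) and utilities (state utilities 0.95–0.10, a
recurrence-cycle utility of 0.42, an sICH disutility of 0.38) accrue per
cycle and are discounted at 5%/year. The headline result is the incremental
cost-effectiveness ratio

```
ICER = ΔCost / ΔQALY
```

judged against willingness-to-pay thresholds of 89,358 CNY/QALY (1× Chinese
per-capita GDP, "highly cost-effective") and 268,074 CNY/QALY (3× GDP).
Uncertainty is handled by a tornado-style one-way analysis over every
published parameter range, deterministic scenarios, and a 10,000-draw
probabilistic sensitivity analysis (PSA) with gamma costs, beta
probabilities/utilities, Dirichlet mRS distribution and lognormal risk and
hazard ratios, all moment-matched from the published point values and 95%
ranges.

## Worked example

```r
library(strokeCEA)
params <- default_parameters()   # bundled published inputs
fit <- run_cea(params)
print(fit)
```

```
Decision-tree + Markov cost-effectiveness analysis
  control      cost     128585 CNY    3.812 QALY    8.034 LY
  argatroban   cost     130903 CNY    4.229 QALY    8.295 LY
  incremental: 2318 CNY, 0.417 QALY, 0.260 LY
  ICER: 5564 CNY/QALY (8908 CNY/LY) -> highly cost-effective
```

Adding argatroban costs 2,318 CNY more per patient over a lifetime but
yields 0.417 extra QALYs (0.260 extra life years), i.e. about 5,600 CNY per
QALY gained — far below the 89,358 CNY/QALY threshold, so the combination
is classified highly cost-effective.

One-way sensitivity and a scenario at the highest listed market price:

```r
tor <- one_way_sensitivity(params)
print(tor, n = 3)
```

```
One-way sensitivity analysis: 36 parameters, base ICER 5564
          parameter     low     high icer_low icer_high   width sign_crossing
1               rr6    0.32     1.30  9349.01   -9358.4 18707.4          TRUE
2               rr0    1.10     2.40 11660.11    2486.8  9173.3         FALSE
3 annual_post_mrs01 2655.00 11311.00  -827.33    8079.1  8906.4          TRUE
```

The treatment-efficacy risk ratios for death (rr6) and full recovery (rr0)
dominate the uncertainty; at rr6 = 1.3 argatroban loses life years and the
ICER turns negative, and at a 2,655 CNY annual care cost for mRS 0–1 the
strategy becomes dominant (cheaper and more effective).

```r
sc <- run_scenario(params, list(drug_price_per_mg = 25.5))
writeLines(render_table2(fit, list("Highest drug price" = sc)))
```

```
                Cost(CNY)         QALY           LY        dCost        dQALY          dLY         ICER
Base case
control           128,585         3.81         8.03
argatroban        130,903         4.23         8.29        2,318         0.42         0.26        5,564
Highest drug price
control           128,585         3.81         8.03
argatroban        136,158         4.23         8.29        7,573         0.42         0.26       18,181
```

PSA (`run_psa(params, n = 10000, seed = 1)`) returns the per-draw
incremental cost/QALY pairs, the cost-effectiveness acceptability curve and
the fraction of draws with positive net monetary benefit at the 1×-GDP
threshold (about 98–99% at the defaults); `plot(psa)` draws the
cost-effectiveness plane, `plot(psa, "ceac")` the acceptability curve.

A thin command-line driver is provided at `inst/cli/stroke_cea.R`
(subcommands `base`, `owsa`, `psa`, `scenario`, `simulate-trial`).

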