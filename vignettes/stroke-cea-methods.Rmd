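---
title: "Methods: a decision-tree + Markov cohort model for argatroban in acute ischemic stroke with early neurological deterioration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree + Markov cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeCEA)
```

## Scope and structure

`strokeCEA` models the lifetime costs and health outcomes of adding a
7-day intravenous argatroban course to standard antiplatelet therapy in
Chinese patients with acute ischemic stroke (AIS) who deteriorate
neurologically within 48 h of onset (END). Two stages are chained:

1. a **decision tree** covering the first 3 months, whose only stochastic
   content is the published summary evidence — the 3-month modified Rankin
   Scale (mRS) distribution of the control arm, per-category risk ratios
   (RR) for the argatroban arm, and arm-specific probabilities of
   symptomatic intracranial hemorrhage (sICH); and
2. a **Markov cohort model** over mRS 0–5 plus death, run in 3-month
   cycles for the remaining 29.75 years (119 cycles), in which treatment
   no longer matters: prognosis depends only on the mRS state reached at
   month 3.

This two-stage shape mirrors how the underlying trial evidence was
generated (a 90-day randomized comparison) and how long-term stroke
prognosis data are published (state-conditional annual risks).

## The decision tree

The control arm's month-3 distribution is used as printed:
(0.116, 0.211, 0.175, 0.231, 0.112, 0.092, 0.063) over mRS 0–6. The
argatroban arm multiplies each category by its RR
(1.63, 0.99, 0.92, 1.07, 0.90, 0.58, 0.64) and renormalizes. The raw
products sum to 1.00062 rather than 1 — rounding noise in the published
ratios — and a Markov model needs a proper distribution, so `apply_rr()`
divides by that sum and records it for audit.

Acute-phase accruals use the month-3 distribution as the whole-period
average (no within-period trajectory is published): cost is the
mass-weighted sum of acute-care costs for mRS 0–1 (12,472 CNY), mRS 2–5
(16,490 CNY) and death (14,133 CNY), plus the expected sICH cost
(probability × 3,012 CNY) and, in the intervention arm, the drug course.
QALYs are 0.25 years of the distribution's expected utility minus the
expected sICH disutility (0.38) held for one cycle — the minimal duration
consistent with the cycle structure, since no duration is published.
sICH affects cost and utility only, not the mRS distribution: the trial's
month-3 distributions already include whatever functional consequences
bleeds had, so shifting states would double-count.

The drug course is 60 mg/day for 2 days plus 20 mg/day for 5 days =
220 mg. We price it at 1.614 CNY/mg, the national centralized-procurement
median, rather than the rounded 1.61 that appears in the input table: only
the former reproduces the published 355 CNY per-patient drug cost
(220 × 1.614 = 355.08). Administration is billed as a continuous infusion
over 7 × 24 = 168 h: one first-hour fee (15.6 CNY) plus 167 additional
hours (1 CNY/h), 182.6 CNY at defaults. Acute-phase quantities occur in
year 0 and are undiscounted.

## The Markov engine

**Events.** Each alive state `j` faces, per cycle, at most one clinical
event. Recurrent stroke occurs with probability
`p = 1 − exp(log(1 − 0.112)/4)` ≈ 0.0293, the published annual incidence
converted by the constant-rate formula. Recurrence is fatal with
probability 0.21; we read this as a per-event case fatality (not an annual
rate needing conversion) because the input table marks only the recurrence
incidence for rate conversion. Survivors are spread uniformly over states
`j..5` — the published equal-redistribution assumption — which also
enforces "no improvement after recurrence" without tunnel states, since
the model parameterizes no spontaneous improvement at all. The
non-recurring fraction dies of non-stroke causes with the age-band
background mortality (0.01266/yr at 66–69 rising to 0.1512/yr at 85+)
converted annual probability → rate → quarter-rate → probability, times
the state-specific death hazard ratio (1, 1, 1.11, 1.27, 1.71, 2.37).
Hazard ratios multiply the *rate*, not the probability: they are rate
multipliers by definition, although at these magnitudes the difference is
below 0.1%. Age advances 0.25 years per cycle and band lookup uses the
exact age at cycle start.

**Accruals.** Per cycle: post-hospitalization annual costs (8,867 CNY for
mRS 0–1, 13,492 CNY for mRS 2–5, at one quarter per cycle) apply to
end-of-cycle survivors; every newly recurring patient incurs the 18,380
CNY event cost, including those who die of it (care is delivered before
death); surviving recurrences take the recurrence utility 0.42 for that
cycle in place of their state utility (an alternative reading — a
multiplicative or subtractive disutility — shifts lifetime totals by
under 1%); recurrence decedents accrue no utility that cycle. Life years
count end-of-cycle survivors.

**Discounting.** Cycle `t` (t = 1..119) is discounted at
`1.05^(−0.25 t)` for costs and effects alike — the standard end-of-period
convention; the source states only the rate. No half-cycle correction is
applied (none is mentioned in the source; the difference is ≤ 2% and is
absorbed by the reproduction tolerances). Life years are reported
discounted, mirroring the QALY arithmetic of the ICER.

## Incremental analysis

`compute_icer()` works on full-precision totals. Classification: cheaper
and more effective is *dominant*; costlier and less effective *dominated*;
otherwise the ICER is compared with 89,358 CNY/QALY (1× 2023 per-capita
GDP; *highly cost-effective* below it) and 268,074 CNY/QALY (3× GDP;
*cost-effective* up to it, *not cost-effective* beyond). Net monetary
benefit is `ΔE × WTP − ΔC`.

## Distribution fitting for the PSA

Published evidence arrives as point value + 95% range. We read every
range as a 95% interval — the RR rows are explicit 95% CIs, and applying
one convention uniformly is the only consistent reading — so
`sd = (high − low)/3.92`, and moment-match:

* **gamma** (costs): `shape = (mean/sd)^2`, `scale = sd^2/mean`;
* **beta** (probabilities, utilities): `ν = m(1−m)/sd^2 − 1`,
  `α = mν`, `β = (1−m)ν`, with the mean clamped to `[1e-6, 1−1e-6]`
  first because the sICH ranges touch 0, and the sd capped just inside
  the Bernoulli bound;
* **lognormal** (risk and hazard ratios): `meanlog = log(point)`,
  `sdlog = (log high − log low)/3.92`. This preserves the median — the
  natural invariant for a ratio whose CI is symmetric on the log scale —
  so the distribution's mean exceeds the point value by `exp(sdlog²/2)`
  (about 2% for the widest RR);
* **Dirichlet** (the control mRS distribution): the mean vector is the
  published distribution; the single concentration budget is the
  across-category average of the implied multinomial size
  `n_i = m_i(1−m_i)/sd_i²` (≈ 303 here, consistent with the trial's arm
  size), a symmetric, reproducible way to reconcile seven per-category
  ranges with one concentration parameter.

Zero-width ranges become point masses. The background mortality table and
the discount rate carry no published distribution and stay fixed in the
PSA (the discount rate is still varied one-way over 0–0.08).

## Sensitivity analyses

**Tornado.** Every scalar parameter with a nonzero published range is set
to its low and high bound in turn — 36 bars: 7 RRs, 6 hazard ratios, 4
event probabilities, 8 utility-block entries, the discount rate and 10
cost fields — and the full model is re-run; bars are ranked by ICER
width. mRS categories are excluded from one-way variation because a
single-category move breaks the sum-to-one composition; their uncertainty
enters through the PSA Dirichlet. Entries record incremental QALYs, LYs
and costs at each extreme, a `less_effective` flag (negative incremental
QALYs *or* LYs at an extreme) and a `sign_crossing` flag (the ICER at an
extreme is negative). At rr6 = 1.3 the model loses life years and gains
costs savings simultaneously, driving the ICER below zero — QALY gains
remain positive because the mRS-0 risk ratio stays at its point value
1.63.

**Scenarios.** `run_scenario()` re-runs the model with named overrides
(drug price, starting age, horizon, a replacement mortality table). The
bundled mortality bands start at 66, so a starting age below that
requires a user-supplied table and otherwise fails loudly; sex-specific
scenarios likewise need user-supplied sex-specific bands. The
highest-market-price scenario uses 25.5 CNY/mg.

**PSA.** `run_psa()` makes `n` independent joint draws (no correlation
structure is published), each run through the full two-arm model. A
master seed spawns one sub-seed per draw, so results are reproducible and
order-independent; structurally invalid draws (a probability outside
[0, 1]) are rejected, redrawn and counted. The acceptability curve is
evaluated on a 0–300,000 CNY grid in 1,000-CNY steps, covering both GDP
thresholds and the low-WTP crossover region near the base-case ICER.
"Highly cost-effective" per draw means positive net monetary benefit at
the 1×-GDP threshold (which subsumes dominance).

## Synthetic data

`simulate_trial()` emulates the *summary* evidence structure the model
consumes: multinomial month-3 mRS counts per arm (the treatment arm's
probabilities are the RR-weighted control distribution) and binomial sICH
counts. `estimate_parameters()` reconstructs the input-table shapes —
proportions, per-category RRs with log-scale delta-method CIs
(Haldane–Anscombe 0.5-cell correction for zero cells, flagged) — and
`parameters_from_trial()` splices them into a base parameter set, so the
whole pipeline can be exercised end to end and parameter recovery can be
tested (a trial of 10^5 per arm recovers the truth-parameter ICER within
a few percent). The generator's defaults are the published study
conditions; what it does **not** emulate is patient-level longitudinal
structure — correlated trajectories, time-varying recurrence risk,
treatment-dependent long-term transitions — so passing tests validate the
estimation-to-model plumbing, not those clinical assumptions.
`random_parameter_set()` draws structurally valid but deliberately varied
inputs (Dirichlet compositions, ordered utilities, synthetic life tables
with age-increasing mortality) for property-based testing.

## Numerical choices and test scale

Occupancy vectors are propagated by exact flow decomposition (recurrence,
case fatality, redistribution, non-stroke death), which matches the
row-stochastic transition matrix to machine precision and lets per-cycle
accrual masses be identified exactly. Mass conservation is enforced to
1e-9 in tests and holds to ~1e-15 in practice. The tests validate the
cohort recursion against an independent individual-level microsimulation
with 100,000 walkers (occupancy after 8 cycles within 3 binomial standard
errors per state; lifetime discounted cost/QALY/LY totals within 3
standard errors), and verify all moment-matching fits against 50,000-draw
sample means. The default test suite and the acceptance script each run
the full 10,000-draw PSA (~2 minutes on one CPU); smaller draw counts are
used where only determinism or plumbing is under test.

## Known limitations

* Transition probabilities after month 3 depend only on the mRS state, not
  on treatment history — inherited from the evidence structure.
* Recurrence risk is constant over time; no secular trend or
  post-recurrence risk elevation.
* The recurrence-cycle utility semantics and the absence of a half-cycle
  correction are modelling conventions chosen for consistency with the
  published description; both are documented above and their impact is
  small relative to the reproduction tolerances.
* Costs are 2023 CNY throughout; no currency conversion or CPI
  re-adjustment is performed.
* The PSA assumes joint independence of all sampled inputs.
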