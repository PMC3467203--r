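---
title: "Model structure and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apixcea)
```

## The decision problem

Patients with non-valvular atrial fibrillation (AF) carry a substantially
elevated risk of ischemic stroke and are treated prophylactically with oral
anticoagulation.  Adjusted-dose warfarin (target INR 2–3) is effective but
raises the risk of intracranial hemorrhage (ICH) and demands laboratory
monitoring; apixaban 5 mg twice daily avoids monitoring and roughly halves
the ICH hazard, at a much higher drug acquisition cost.  `apixcea`
implements a Markov cohort model that asks whether the hemorrhage reduction
and monitoring savings offset apixaban's price, from the US Medicare
perspective in 2012 dollars, for a cohort entering at age 65 with a mean
CHADS~2~ score of about 2.

## State space and transitions

A living patient is described by four attributes: current antithrombotic
treatment (the strategy anticoagulant, or aspirin after a major
hemorrhage), ischemic-stroke sequela (none / minor / major), ICH sequela
(none / minor / major), and MI history.  Expanding the attributes gives 36
living states plus one absorbing dead state; `model_states()` enumerates
them and `build_transitions()` wires one transition row per (state, event)
pair.  The cohort engine and the patient-level microsimulation consume the
same transition table, so any divergence between them is a bug by
construction.

Cycles last two weeks and at most one event occurs per cycle.  The event
families are:

* **Ischemic neurologic events** at 1.05 %/yr on warfarin (hazard ratio
  1.0 on apixaban, relative risk 2.08 on aspirin).  28 % of these are
  TIAs, costed as reversible events with no sequela; the remaining 72 %
  are strokes split fatal / major / minor / no-residual (RIND) by
  treatment-specific severity distributions (8.2/40.2/42.5/9.1 on an
  anticoagulant; 17.9/30.0/41.0/11.0 on aspirin — the printed aspirin
  fractions sum to 99.9 and are renormalised).  A second minor stroke
  escalates to the major-stroke state; a second major stroke is fatal.
* **ICH** at 0.80 %/yr on warfarin (HR 0.42 on apixaban, RR 0.87 on
  aspirin), split 36.4/14.1/49.5 fatal/major/minor.  Survivors carry a
  permanent neurological sequela.
* **Extracranial hemorrhage (ECH)** at 3.09 %/yr (HR 0.69 / RR 0.87) and
  **clinically relevant minor bleeding** at 2.55 %/yr (RR 0.69 / 0.87):
  temporary states with one-time costs and transient utility decrements.
* **MI** at 0.61 %/yr (HR 1.0 on apixaban, RR 1.42 on aspirin), leaving a
  permanent history flag.
* **Non-event death** from an age-specific life table (below).

Any ICH, or a (non-fatal) ECH, on an anticoagulant causes a permanent
switch to aspirin; sequelae are monotone — no transition ever improves a
patient's neurological state.

## Probabilities, age dependence and mortality

Annual rates `r` (%/yr) convert to per-cycle probabilities with the
constant-hazard rule `p = 1 − exp(−(r/100) · 14/365.25)`
(`annual_rate_to_cycle_prob()`).  Competing events are converted
independently and combined with an explicit no-event remainder; the engine
aborts if the combined per-cycle event probability ever reaches 1, which
under the published ranges it never approaches (worst case ≈ 0.06).

Stroke, ICH and MI risks rise with age by factors of 1.4, 1.97 and 1.3 per
10 years of life.  `age_adjust()` applies these **in discrete decade
steps** (`rr^floor((age−65)/10)`): risk is flat within a decade of life
and steps up at ages 75, 85 and 95, the way a table-driven cohort model
indexes risk by age band.  A continuous exponent is available
(`method = "continuous"`); with it the late-life ICH burden grows smoothly
and the incremental life-year gain of apixaban roughly doubles, which
overshoots the incremental outcomes this model is calibrated to, so the
step form is the default.

Background (non-event) mortality comes from a bundled life table and is
multiplied, on the hazard scale, by 1.3 for AF, or by 2.3 for AF patients
with a prior **ischemic stroke** sequela.  Two points deserve emphasis:

* The two ratios are read as alternative multipliers of the same
  population baseline (the parameter ledger lists "non-event death with
  NVAF, 1.3" and "with NVAF and stroke, 2.3" side by side), so 2.3
  *replaces* 1.3 rather than stacking on it.  Setting
  `stroke_mort_composition = "multiplicative"` in the scenario stacks
  them (1.3 × 2.3) instead.
* ICH-only survivors keep the 1.3 ratio: in this model's vocabulary
  "stroke" denotes the ischemic stroke states (including stroke-and-ICH).
  Their excess risk is already expressed through the fatal ICH fraction
  and their chronic disease costs.

Working on the hazard scale (`h = −log(1−q)`, multiply, convert back)
keeps the result a probability even at ages where `2.3 × q` would exceed 1.

### The life table

The model needs single-year all-cause mortality for ages 65–100.  The
bundled file `life_table_us2012_synthetic.csv` is a synthetic
reconstruction: log-linear interpolation between 2012-era US all-cause
mortality anchor probabilities (0.0132 at 65 rising to 0.348 at 100,
implying a period life expectancy at 65 of about 18.6 years).  It stands
in for the census-based table the model design calls for and is
replaceable through the scenario file's `life_table` field, which is the
recommended way to study sensitivity to this input.

## Economics

Each cycle charges a bi-weekly treatment cost (warfarin + INR monitoring
$18, apixaban $95, aspirin $0.30), a chronic-state cost (minor stroke
$1,232; moderate-to-severe stroke $2,683; ICH $2,835; the combined
stroke-and-ICH state $3,595, which *replaces* the two separate costs; MI
history adds $152), and one-time event costs in the cycle an event occurs
(RIND/TIA $6,562; minor stroke $9,956; moderate-to-severe stroke $14,783
— also charged for fatal strokes, which have no separate printed cost;
ICH $41,645; ECH $5,830; minor bleed $42; MI $20,357; non-event death
$5,000).

Utilities multiply: treatment utility (0.987 / 0.994 / 0.998 for warfarin
/ apixaban / aspirin) times sequela utilities (major neurological event
0.39, minor 0.75, MI history 0.84).  Coexisting sequelae combine
multiplicatively by default; `utility_combination = "minimum"` instead
takes the worst sequela utility, for users who prefer that convention.  A
non-fatal ECH subtracts 0.16 for its full cycle and a minor bleed 0.16
for 2 of the 14 days; realised cycle utilities are clamped to [0, 1].
ICH carries no additional transient decrement — its utility loss is the
permanent sequela weight.

Rewards accrue on beginning-of-cycle occupancy, with event rewards charged
on the transition; there is no half-cycle correction by default (with
2-week cycles the correction moves lifetime totals by well under 1 %; a
`half_cycle` scenario flag enables an occupancy-averaging correction for
exploration).  Costs and health outcomes discount at 3 %/yr as
`(1.03)^(−k·14/365.25)` for cycle `k`, and the cohort runs 913 cycles
(35 years, ages 65–100), the horizon used as "lifetime".

The apixaban 2-week cost is $95 in the base case (the value in the
parameter ledger); the $103 wholesale-acquisition figure mentioned
alongside it is available as `default_scenario("apixaban_cost_103")`.
Fatal fractions for ECH and MI are scenario fields
(`fatal_ech_fraction`, `fatal_mi_fraction`) defaulting to 0 — those
events kill only through background mortality — because no published
split exists; they are implementation defaults, not literature values.

## Sensitivity analyses

`one_way()` sweeps a parameter across its published plausible range and
then bisects (to 10⁻⁶ of the range) for the value where incremental cost
crosses zero (loss of dominance) and where net monetary benefit at the
willingness-to-pay threshold crosses zero.  `two_way()` classifies an
n×m grid (dominant / cost-effective / not cost-effective), by default
over the Medicare-registry stroke-rate range 0.61–5.82 %/yr against the
ICH-rate range.  `horizon_sweep()` truncates the horizon and re-runs the
comparison.

`run_psa()` draws every parameter that has a published range from a
triangular(low, base, high) distribution via inverse-CDF sampling
(`sample_triangular()`), runs both strategies on the same draw, and
summarises the cost-effectiveness plane.  Sampling choices:

* parameters are independent (no correlation structure is published);
* the four stroke severity fractions are sampled and renormalised to sum
  to 100 %; the minor-ICH fraction, which has no published range, is the
  remainder after the sampled fatal and major ICH fractions;
* structural parameters without ranges (the per-decade RRs, the TIA
  fraction) stay fixed;
* the discount rate has a published range (0–5 %) and is sampled like any
  other parameter;
* "cost-effective at WTP" means net monetary benefit
  `50,000 · ΔQALY − Δcost > 0`, which handles all four plane quadrants
  coherently (a dominated draw can never qualify).

## The microsimulation oracle

`simulate_patients()` draws individual trajectories from the exact
per-cycle transition probabilities of the cohort engine.  Each patient
owns an independent xoshiro256++ RNG stream seeded from the master seed,
so patient *i*'s trajectory is invariant to the cohort size and results
are reproducible across platforms.  Sample means of discounted cost,
QALYs and life-years are unbiased estimates of the cohort totals; the
test suite requires agreement within three standard errors at 200,000
patients, and a χ² test that first-cycle event draws match the analytic
event mix.  `export_event_histories()` emits the trajectories as a
long-format table for downstream demonstrations (e.g. time-to-event
analyses on synthetic data).

The microsimulation is a validation oracle and synthetic-data generator,
not a second model: it has no individual-level heterogeneity beyond age
progression, because the cohort model it validates is homogeneous.

## What the synthetic inputs do and do not show

The generator's default scenario *is* the study condition set: every
rate, cost, utility and range comes from the published parameter ledger,
and the life table approximates 2012 US mortality.  Passing tests
therefore show that the implementation reproduces the published model's
behaviour under its stated inputs.  They do not validate the model
against real-world AF cohorts: trial-derived event rates (from a
population with ~66 % time in therapeutic INR range), a single starting
age, and cost structures frozen in 2012 dollars all limit external
validity, as does the assumption that every major hemorrhage permanently
ends anticoagulation.

## Numerical choices and degenerate inputs

* Probability invariants are enforced at run time: every transition
  probability must lie in [0, 1] and each state's outgoing mass must leave a
  non-negative no-event remainder, else the run aborts.
* Degenerate triangular distributions (low = mode = high) return the
  point mass, so a PSA over collapsed ranges reproduces the
  deterministic base case to machine precision.
* Bisection reports no threshold when the range does not bracket a sign
  change (a flat response is an answer, not an error).
* Zero event rates and a zero life table are valid inputs (the cohort
  then never moves), used by the test suite as conservation checks.
* Ages beyond the life table clamp to its last row; the scenario
  validator requires the table to cover the whole horizon, so clamping
  only matters for user-supplied short tables.

## Problem sizes

The deterministic base case iterates 37 states over 913 cycles
(milliseconds).  The probabilistic analysis uses 10,000 iterations, the
published size.  The microsimulation oracle uses 200,000 patients in the
acceptance checks — enough to pin the three-standard-error comparison to
roughly ±0.03 QALY — and smaller cohorts (30,000–100,000) in routine
tests.

## Known limitations

* The model inherits every structural simplification of its source:
  one event per 2-week cycle, independent competing events, homogeneous
  cohort, no INR time-in-range modelling, no other comparators
  (dabigatran, rivaroxaban), no societal costs.
* The bundled life table is a smooth synthetic approximation, not an
  official table; absolute (though much less so incremental) outcomes
  shift by a few percent under plausible alternatives.
* Fatal ECH/MI fractions default to zero for want of published values;
  users studying those channels should set the scenario fields
  explicitly.
* The decade-step age adjustment makes event risk discontinuous at ages
  75, 85 and 95; the continuous option exists but alters calibration.
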