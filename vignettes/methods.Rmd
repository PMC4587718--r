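---
title: "Model and methods: genetic-test-motivated warfarin adherence in atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afcea)
```

## The decision problem

A cohort of 1000 atrial-fibrillation patients has declined prescribed
warfarin and receives aspirin instead.  `afcea` compares usual care with
a strategy that genotypes every patient at the 4q25 locus and assumes a
fraction *a* of the 40 % who test positive is motivated to start
warfarin.  The output is the incremental discounted cost and
quality-adjusted life-years (QALYs) of the test strategy over a 5-year
horizon, its ICER or dominance status, and the adherence thresholds at
which it becomes cost-effective and cost saving.

## State space and annual event process

Eight health states: `WELL_ASPIRIN`, `WELL_WARFARIN`,
`POST_STROKE_WARFARIN`, `POST_STROKE_ASPIRIN`, `POST_ICH`, `POST_BLEED`,
`RECURRENT_STROKE`, `DEAD`.  Each live state implies a current therapy,
and each year a patient faces mutually exclusive events with additive
probabilities:

* ischemic stroke, at 4.5 %/yr on aspirin and 4.5 x 0.48 = 2.16 %/yr on
  warfarin, fatal with probability 0.179 (aspirin) or 0.082 (warfarin);
* major hemorrhage, at 2.5 %/yr on warfarin and 2.5 x 0.59 = 1.475 %/yr
  on aspirin; 20 % of major hemorrhages are intracranial (ICH; fatal
  fraction 0.364), the rest extracranial (fatal fraction 0.049);
* for warfarin decliners on aspirin, conversion to warfarin at the
  applicable annual rate (see below).

Care rules: stroke survivors move to `POST_STROKE_WARFARIN` (decliners
convert after a stroke); a second stroke leads to the absorbing-while-
alive `RECURRENT_STROKE`; ICH survivors discontinue warfarin permanently
(`POST_ICH`, on aspirin); extracranial-bleed survivors discontinue
warfarin for the event year (`POST_BLEED`) and return to `WELL_ASPIRIN`.
There is no background (non-event) mortality: the published inputs
specify only event fatality fractions, and adding life-table mortality
would change the published results the package reproduces.

Costs (2005 USD) and utilities attach to states and events exactly as
published: drug costs $10/yr (aspirin) and $180/yr (warfarin); one-time
event costs ($12,130 fatal stroke; $9,610/$9,667 non-fatal stroke by
therapy; $31,810 ICH; $3,620 extracranial bleed); monthly follow-up
costs for post-stroke ($2,168/$2,652 by therapy), recurrent-stroke and
post-ICH ($4,690) states; utilities 0.998/0.987 (well, by therapy),
0.426/0.476 (post-stroke, by therapy), 0.4 (post-ICH), 0.12 (recurrent
stroke), 0 (dead).

## Intra-cycle accounting conventions

With one-year cycles, the published description leaves the within-year
accounting open.  The package adopts one fixed set of conventions,
chosen once by calibrating the model's adherence sweep against the
published sweep table (whose cost column is exactly affine in adherence,
saving(a%) ~ 17,001 a − 89,333) and then used everywhere:

* **Drug cost** — the event year is charged the pre-event therapy's
  annual drug cost (start-of-cycle occupancy).
* **Utility** — the event year is valued at the destination state's
  utility (end-of-cycle occupancy): a stroke year scores the post-stroke
  utility, a death year scores 0.
* **Follow-up (monthly) costs** — accrue on the mid-cycle occupancy, the
  average of start- and end-of-cycle occupancy: events fall mid-year on
  average, so the event year accrues half a year of follow-up cost, and
  every subsequent year in the state accrues twelve months.  Follow-up
  costs persist for as long as the state is occupied, through the
  horizon.
* **Conversion** — the annual conversion probability applies to the full
  state occupancy as a competing outcome, mutually exclusive with the
  index events — the same additive-competing-risks convention used for
  stroke versus hemorrhage.  (Gating conversion on the event-free
  remainder instead shifts the base-case ICER at 2.1 % adherence by
  about +2 % away from the published value; the ungated convention
  reproduces it to 0.4 %.)
* **Discount timing** — `discount_factor(rate, t)` = (1 + rate)^(−t).
  By default the first model year is undiscounted (exponent 0).  The
  single structural switch `discount_from` shifts every exponent by one;
  the published figures reproduce under `discount_from = 1`, which the
  acceptance script and the reproduction tests therefore use.  No
  half-cycle correction is applied to utilities.
* **Test cost** — charged once per tested person at time zero,
  undiscounted (testing precedes the first cycle).

Two corner rules needed a decision the publication does not determine:
stroke survivors among post-ICH patients stay on aspirin
(`POST_STROKE_ASPIRIN` — warfarin is contraindicated after ICH), which
is also where the published aspirin post-stroke utility (0.426) and
monthly cost ($2,168) act; and fatal ICH / fatal extracranial bleeds
carry the same one-time cost as their non-fatal forms, since only fatal
ischemic stroke has a published fatal-event cost.  Patients in
`RECURRENT_STROKE` remain there, at warfarin event rates, with further
strokes tallied but not changing state.

"Stroke events prevented" in the headline event differential counts
*index* strokes — strokes incident from states with no prior ischemic
stroke — i.e. first strokes per patient; strokes recurring in
post-stroke states are tallied separately in the traces.

## Parameters

All inputs live in one flat parameter set (`default_parameters()`), and
a YAML configuration with the same keys can override any of them
(`load_parameters()`); probability-like keys accept percent strings
("4.5%").  Structural constants: cohort 1000, horizon 5 one-year cycles,
discount 3 %/yr, test-positive fraction 0.40, background conversion
2.5 %/yr with multipliers 2.0 (test-positive) and 0.5 (test-negative).
Two values the publication does not print are design choices, both
configurable: the genetic-test cost, $100 (the approximate two-SNP
Medicare reimbursement, inside the $50–$200 sensitivity range), and the
willingness-to-pay threshold, $50,000/QALY (the conventional US value
consistent with labelling ~$47,000/QALY cost-effective).  Costs are
fixed in 2005 USD; a global `cost_multiplier` stands in for inflation
adjustment.  Validation enforces all invariants (probabilities and
utilities in [0,1], positive relative risks, non-negative costs, ranges
bracketing their base values, derived therapy products in [0,1]) and
reports every violation at once.

## Sensitivity analyses

Seven quantities vary: the four event rates/relative risks, the test
cost, and grouped cost (x0.5–x1.5) and utility (x0.8–x1.2) multipliers.
The grouped multipliers move all event/drug costs and all
non-fatal-event-state utilities simultaneously, as single factors — the
healthy-state utilities are held fixed.  The tornado evaluates each
quantity at its bounds at 5.25 % adherence, where the base case is
approximately cost neutral, so a bar shows how far one parameter alone
moves the ICER.  The CHADS2 stratification replaces the aspirin stroke
rate with per-score rates at the same adherence; the packaged grid
(1.9–18.2 %/yr for scores 0–6) is an external-sourced default from the
CHADS2 validation literature and is supplied via configuration, not
hard-coded.

The PSA draws all seven quantities independently from triangular
distributions (mode at base, bounds at the ranges) via inverse-CDF
sampling, evaluates the comparison at 20 % adherence per draw, and
reports cost-effectiveness-plane quadrant fractions.  Variance
contributions use the squared Pearson correlation between each
parameter's draws and the incremental net monetary benefit at the
configured willingness-to-pay, normalized to sum to 1: the published
description of the decomposition ("correlation between the variance of
each parameter and the variance of the outcome") is not a defined
estimator, so this standard first-order R² share is adopted and
documented.  Fatality fractions are not varied (no ranges are
published for them).

## The microsimulation oracle

`simulate_cohort()` realises the identical annual process as independent
patient trajectories: one categorical draw per patient-year over the
exact transition flows, with the same accrual rules and discounting.
Each patient consumes a fixed block of uniforms from a single seeded
stream (one for sub-cohort membership, one per cycle), so enlarging the
cohort never changes earlier patients' draws and any patient can be
replayed in isolation with `simulate_patient()`.  Because the cohort
model is the exact expectation of this process, microsimulation means
must converge to cohort totals at rate 1/sqrt(n) — the package's central
validation property, tested at n = 10^5 against 3-standard-error bounds
for the base case and perturbed configurations.

What the simulator emulates is the model, not reality: patients are
homogeneous within sub-cohorts (no age, sex or per-patient CHADS2
covariates), event probabilities are constant in time, adherence is a
single initial fraction rather than a behavioural process, and there is
no background mortality or test error.  Agreement between the two
engines therefore validates the implementation, not the epidemiology.

## Numerical choices

Transition rows are checked to sum to 1 within 1e-12, and infeasible
combinations (event probabilities plus conversion exceeding 1) are
rejected at build time.  Threshold searches bisect on [0, 1] to an
absolute tolerance of 1e-5; the affine dependence of incremental cost
and QALYs on adherence (verified to 1e-9 by superposition tests) makes
each crossing unique.  Cost-effectiveness thresholds are located via the
net-monetary-benefit root, which coincides with ICER = WTP where
incremental QALYs are positive and handles the dominance region without
ratio singularities.  The engine is validated against an independent
brute-force oracle that enumerates every event path for one patient over
up to 3 cycles (agreement to 1e-9).  Dominance classification treats
differences below 1e-9 as zero.

Problem sizes in the test suite and acceptance script — 10^5-patient
microsimulations, 10,000-draw PSA, full tornado/CHADS2/sweep grids —
are the analysis's own natural sizes; the whole suite runs in about a
minute on one CPU.

## Known limitations and published inconsistencies

* The model has no NOAC arm, no INR/time-in-therapeutic-range dynamics,
  no test errors, and no modelling of partial adherence within warfarin
  users; currency is 2005 USD throughout.
* In the test arm at adherence 0 the population-average conversion rate
  is 0.4 x 5 % + 0.6 x 1.25 % = 2.75 %/yr, not 2.5 %: the published
  multipliers are not rebalanced, and neither are the defaults here.
* The publication reports both "~$40,000" and "~$47,000" for the ICER at
  a 3 % aspirin stroke rate in different sections; the package simply
  reports its computed value for that scenario rather than targeting
  either number.
* The published sweep table prints 8.8 QALYs gained at 20 % adherence
  while the accompanying text rounds it to "a net gain of 9 QALYs"; the
  package reports unrounded values.
* Whether adherent warfarin starters can spontaneously discontinue is
  not specified; here they discontinue only after a major bleed.
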