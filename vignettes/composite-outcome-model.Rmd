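---
title: "The daily composite-outcome model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The daily composite-outcome model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coherentHF)
```

This vignette is the package's own account of what it computes and why the
open design questions were settled the way they were. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model

Composite outcomes that mix mortality with healthcare utilization are hard
to read from separate rate tables: a group can simultaneously have higher
mortality and fewer readmissions, and the net clinical picture only
appears when both are placed on one timeline. The COHERENT representation
resolves this by reducing each patient's follow-up to one **clinical state
per day**, drawn from a mutually exclusive, priority-ordered list:

```{r}
clinical_states()
```

Day 0 is the index ED arrival; the horizon is fixed (30 or 365 days), so a
cohort of $n$ patients contributes exactly $n \times H$ patient-days and
every daily column of the cohort occupancy matrix sums to one. The matrix
is rendered as a stacked-area chart — mortality at the base of the stack,
time at home on top — and summarised per patient by day counts
(`summarize_journey()`), including the share of time alive and out of
hospital that was spent at home,

$$\frac{\text{days at home}}{H - \text{days dead} - \text{days in hospital}},$$

defined as 1 when the denominator is zero (death on day 0).

### Day-counting conventions

These conventions are load-bearing and fixed:

* **Hospitalizations** occupy the half-open interval
  [admission, discharge): length of stay equals discharge date minus
  admission date, a same-day discharge occupies its admission day
  (minimum one day), and the discharge day itself is available for the
  next state. This is the only convention under which a stay of median
  length 8 contributes 8 hospital days.
* **ED, day-hospital and outpatient episodes** occupy every calendar date
  they touch; a same-day ED visit is 1 day. ED stays therefore average
  around 1.7 days — an arrival before midnight followed by a morning
  discharge touches two dates — which matches how ED "days" arise in
  administrative data.
* **Ties** are resolved by the fixed priority order: a same-day ED arrival
  plus admission renders as hospital; an outpatient visit during a
  readmission renders as readmission; death always wins, from the death
  day to the horizon.
* Days after death count as dead, never as utilization.

The timeline anchor (index ED arrival) makes the journey window a fixed
$H$ days per patient including the index episode, which is what makes
"total patient-days = $n \times H$" an identity. Event-rate cut-offs,
by contrast, are anchored at **index discharge** (see below); the two
anchors serve different quantities and are deliberately not unified.

## Cohort rules

A patient enters the cohort through their first ED visit of the target
calendar year that carries an HF classification, either directly (ICPC-2
`K77`) or on the hospitalization linked to that visit (ICD-10-CM I11.0*,
I13.0*, I13.2*, I50*, present on admission). Classification is by
diagnosis position: position 1 is primary HF; any later position,
secondary. Two exclusions mirror standard administrative practice: a
hospitalization whose only HF codes are *not* present on admission is
new-onset HF (the condition arose in-stay, not a chronic HF encounter),
and an ED `K77` without a defined position cannot be classified at all.

Two rules are interpretations where the source conventions are silent,
both flagged in the function documentation:

* **ED-to-admission linkage**: a hospitalization starting on, or one
  calendar day after, the ED end date belongs to the same care contact
  (midnight-crossing admissions).
* **Multi-visit patients** are anchored at their first qualifying ED visit
  of the year.

## Outcome statistics

Event rates are **crude cumulative incidences**: the share of all patients
with at least one qualifying event in (discharge, discharge + t],
t ∈ {30, 365}. Death does not remove patients from the denominator and no
competing-risk adjustment is applied — this matches how n (%) rates are
reported from claims data, and it is the scale on which the generator's
defaults are calibrated. Mortality at a cut-off is cumulative (in-hospital
deaths count), while in-hospital mortality is computed separately from the
index disposition. Survival uses the Kaplan–Meier product-limit estimator
and the two-group log-rank test via the `survival` package; the test suite
cross-checks both against hand-rolled product-limit and
observed-minus-expected oracles, and checks the log-rank p-value against a
label-permutation distribution. Group comparisons dispatch on a
caller-declared scale (t test, Mann–Whitney, or chi-square without
continuity correction); normality is a modelling decision of the analyst,
not auto-detected.

## Costing

Each episode's cost is the sum of three components of a full-costing
system: directly imputable costs, catalog activity (quantity × unit
cost), and a **residual** — overheads that cannot be attributed to any
single episode. The residual pool is transferred to episodes *per diem*
(proportional to occupied days). The true institutional imputation
criteria behind such systems are not public; per-diem allocation is the
standard full-costing fallback and is the one weight `allocate_residual()`
implements.

All monetary arithmetic is carried at cent precision with
largest-remainder reconciliation (`split_amount()`), so conservation is
exact at every level: line items sum to episode totals, episode totals to
journey totals, journey totals to group totals, and daily cost curves end
at the journey total to the cent. Daily curves spread each episode's total
uniformly over its occupied days; no intra-episode cost profile is
assumed.

Journey cost summaries divide by $n$ patients and by $n \times H$
patient-days; because the horizon is fixed, mean cost per patient-day
times $H$ equals mean cost per journey exactly. Mean days spent at the
ED / in hospital are computed over patients with at least one such
episode (users), the more informative of the two possible denominators.

## The synthetic generator

The generator exists because the record-level data behind the published
aggregates are access-restricted. It emulates the *structure* the
analysis consumes, with defaults set to the published reference values
(`synthetic_params()`), per HF group and disposition arm:

* **Index contact**: ED arrival uniform over 2018; ED duration of 1–3
  calendar dates with P = (0.44, 0.46, 0.10), mean 1.66 days; for the
  hospitalized arm a linked admission on the ED end date with planted
  pHF/sHF diagnosis codes — a configurable share of patients (13 % pHF,
  47 % sHF) carry no HF code in the ED and qualify only through the
  admission's present-on-admission codes, exercising that cohort pathway.
* **Length of stay**: log-normal matched on the log scale to median 8 and
  IQR 6–12, rounded to whole days (minimum 1).
* **Death**: with probability `p_inhosp_death` the patient dies in the
  index stay. Survivors draw a post-discharge death time from a
  **two-piece constant hazard** (pieces 0–30 and 31–365 days) solved
  analytically from the two printed cumulative mortalities, conditioned on
  having survived the stay: $q = (p - p_{\text{inhosp}})/(1 -
  p_{\text{inhosp}})$. This reproduces the early-divergence-then-parallel
  survival shape without inventing a parametric family, and makes the
  *crude* 30-day and 1-year mortality equal their planted values exactly
  in expectation.
* **Readmissions and ED revisits**: first-event times from the same
  two-piece construction (calibrated to the printed 30-day and 1-year
  probabilities, conditioned on surviving the stay), subsequent events
  from the late-period hazard, stays non-overlapping, everything stopped
  at death.
* **Outpatient and day-hospital activity**: negative-binomial visit
  counts (printed mean/SD) and Poisson day-hospital counts (printed
  episodes per patient-year), placed uniformly over the follow-up year
  while alive.
* **Costs**: log-normal per episode kind, moment-matched to the printed
  per-episode means/SDs, split into direct/catalog/residual line items at
  cent precision with the catalog identity amount = quantity × unit cost
  holding exactly.
* **Randomness**: every patient draws from an RNG substream derived from
  the seed and the patient index, so output is byte-identical under a
  fixed seed and enlarging the cohort never perturbs earlier patients.

### What the generator does *not* emulate

Passing tests on synthetic data show the pipeline is internally coherent
and recovers known inputs; they do not validate the clinical realism of
any particular hospital's data. Known simplifications:

* LOS, costs and death are independent given group; real data correlate
  all three (sicker patients stay longer, cost more, die more).
* Because recurrent events are stopped at death but calibrated marginally,
  observed 1-year readmission/re-ED rates and outpatient counts run a few
  points below their planted values (death censoring); 30-day rates and
  all recovery-tested quantities are unaffected. This is the honest
  behaviour of a point process stopped at death, not a calibration error.
* Diagnosis-code diversity is minimal — just enough to exercise every
  classification branch; real coding noise (misspelled codes, position
  drift) is out of scope.
* The 15 ED deaths of the reference cohort are not stratified by HF group
  in the source aggregates; the defaults split them 8/7.

## Numerical choices

* Dates are ISO-8601 calendar dates; all interval logic is whole days.
* Occupancy matrices must be column-stochastic to 1e-9; the stacking layer
  refuses anything worse before rendering.
* Cent-level largest-remainder rounding breaks ties by position (earlier
  episode first), making allocations deterministic.
* Code normalization strips dots and upper-cases before prefix matching,
  accepting both ICD-10-CM dialects (`I11.0` and `I110`).
* Degenerate inputs are defined, not rejected: death on day 0 yields an
  all-dead journey with home-share 1; an empty cost-item list yields a
  zero episode cost; identical categorical distributions yield chi-square
  0 with p = 1.

## Problem sizes

The test suite exercises the engine on 1,000 randomly constructed
journeys, ledger conservation on generated cohorts of a few hundred
patients, and parameter recovery at 1,500 patients per group (3-SE
binomial bands); the acceptance script re-runs recovery at 5,000 per
group, the size at which the 3-SE bands are tight enough to be
informative (±1.5–2 percentage points on the planted rates). These sizes
were chosen so each property is tested at the smallest scale at which its
sampling error is decisive.

## Limitations

The package models a single hospital's administrative universe: no
multi-centre linkage, no cause-specific event attribution, no
competing-risk estimators, no regression adjustment — none of which the
underlying design uses. Absolute synthetic costs inherit whatever the
configured distributions say and should not be read as forecasts;
relative comparisons between groups are the meaningful output.
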