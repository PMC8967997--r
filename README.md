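# coherentHF

Outcomes, healthcare resource use and costs of heart-failure patient
journeys, built from episode-level hospital administrative records.

## The problem

Heart failure (HF) appears in hospital discharge data in two guises: as the
principal diagnosis of the encounter (**pHF**) or coded in a secondary
position while something else — pneumonia, sepsis, COPD — drives the
admission (**sHF**). The two populations differ in comorbidity, early
mortality, resource use and cost, but comparing them requires stitching
together emergency-department (ED) visits, hospitalizations, day-hospital
and outpatient activity, vital status and per-episode cost ledgers into a
single per-patient timeline. `coherentHF` implements that pipeline for
epidemiologists and health-services researchers working with
minimum-basic-dataset–style exports:

* **Cohort construction** — inclusion through ED activity in a target
  calendar year, HF identification via ICD-10-CM codes I11.0\*, I13.0\*,
  I13.2\* and I50\* (present on admission only) or the ICPC-2 `K77` ED
  code, pHF/sHF classification by diagnosis position, exclusion of
  new-onset HF and of unclassifiable `K77` visits, and partition into
  hospitalized / discharged-home / died-in-ED arms.
* **The COHERENT composite outcome** (Clinical Outcomes, HEalthcare
  REsource utilizatioN and relaTed costs) — every patient-day of a fixed
  follow-up horizon (30 or 365 days from the index ED arrival) is assigned
  exactly one clinical state from a priority-ordered list

  `DEAD > hospital (index) > hospital (readmission) > ED (index) > ED
  (revisit) > day hospital > outpatient visit > at home`,

  and cohort occupancy is plotted as a stacked-area chart: each day a
  column summing to 100 % of patients.
* **Outcome statistics** — crude event rates (death, readmission, ED
  revisit, first hospitalization) in the window
  (discharge, discharge + t] for t ∈ {30, 365}, Kaplan–Meier survival
  S(t) = ∏<sub>t<sub>i</sub>≤t</sub>(1 − d<sub>i</sub>/n<sub>i</sub>),
  the two-group log-rank test, and Student's t / Mann–Whitney / chi-square
  group comparisons.
* **Full-costing arithmetic** — per-episode costs split into direct,
  catalog (quantity × unit cost) and per-diem–imputed residual components;
  roll-ups to journey, clinical-status and per-episode-kind totals with
  exact cent-level conservation (largest-remainder rounding).
* **A seeded synthetic cohort generator** — the raw records behind the
  published aggregates are access-restricted, so the generator emulates
  their structure (two-piece constant-hazard mortality matched to 30-day
  and 1-year rates, log-normal lengths of stay and episode costs,
  overdispersed outpatient activity, planted diagnosis codes) with
  defaults set to the published reference values, making every stage of
  the pipeline testable end to end.

## Worked example

```r
library(coherentHF)

p <- synthetic_params()           # published-default study conditions
for (g in names(p$groups)) {      # scale down for a quick run
  p$groups[[g]]$hospitalized$n <- 400L
  p$groups[[g]]$ed_home$n      <- 150L
  p$groups[[g]]$died_in_ed$n   <- 3L
}
cohort <- generate_cohort(p, seed = 42)

strata <- build_strata(cohort$episodes, cohort$vitals, 2018)
strata
#> Cohort strata: 1106 included patients
#>                          hf_group
#> arm                       pHF sHF
#>   DIED_IN_ED                3   3
#>   DISCHARGED_HOME_FROM_ED 150 150
#>   HOSPITALIZED            400 400
```

One-year outcome rates for the hospitalized arm (crude: patients with at
least one event within 365 days of index discharge, over all patients):

```r
rates <- outcome_table(strata, cohort$episodes, cohort$vitals)
subset(rates, arm == "HOSPITALIZED" & cutoff_days == 365)
#>          arm hf_group       event cutoff_days numerator denominator   rate
#> HOSPITALIZED      pHF       DEATH         365       107         400 0.2675
#> HOSPITALIZED      pHF READMISSION         365       176         400 0.4400
#> HOSPITALIZED      pHF RE_ED_VISIT         365       239         400 0.5975
#> HOSPITALIZED      sHF       DEATH         365       117         400 0.2925
#> HOSPITALIZED      sHF READMISSION         365       149         400 0.3725
#> HOSPITALIZED      sHF RE_ED_VISIT         365       216         400 0.5400
```

The sHF group dies more and is readmitted less over the year — the pattern
the generator's defaults encode. Journey costs over the fixed 365-day
horizon:

```r
ec    <- episode_cost_table(cohort$costs)
costs <- journey_cost_summary(strata[strata$arm == "HOSPITALIZED", ],
                              cohort$episodes, ec)
costs$by_group[, c("hf_group", "n_patients", "total_cost",
                   "mean_cost_per_journey", "mean_cost_per_patient_day")]
#> hf_group n_patients total_cost mean_cost_per_journey mean_cost_per_patient_day
#>      pHF        400    2899639              7249.098                  19.86054
#>      sHF        400    2957641              7394.103                  20.25782
```

`mean_cost_per_journey` is total cost over patients;
`mean_cost_per_patient_day` divides by n × 365 patient-days (the two are
proportional by construction, since every journey spans the same horizon).
The composite-outcome chart and its numeric stacking layer:

```r
js <- cohort_journeys(strata[strata$hf_group == "sHF" &
                             strata$arm == "HOSPITALIZED", ],
                      cohort$episodes, cohort$vitals, horizon = 365L)
cp <- coherent_plot(occupancy(js), file = "coherent_sHF.png")
head(cp$data)   # day, state, fraction, ymin, ymax — testable without pixels
```

A thin command-line driver over the same functions ships in
`inst/scripts/coherent-cli.R` (`simulate`, `build-cohort`, `trajectories`,
`outcomes`, `costs`, `plot` subcommands).

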