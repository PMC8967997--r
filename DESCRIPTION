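Package: coherentHF
Title: Patient-Journey Outcomes, Resource Use and Costs for Heart Failure Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds heart-failure cohorts from episode-level administrative
    records (emergency department visits, hospitalizations, day-hospital and
    outpatient visits), classifies patients by primary versus secondary heart
    failure diagnosis, converts each patient journey into a daily sequence of
    mutually exclusive clinical states (the COHERENT composite-outcome model),
    computes crude event rates, Kaplan-Meier survival and group comparisons,
    aggregates full-costing episode expenditures into per-journey, per-status
    and per-episode summaries, and renders the stacked-area composite-outcome
    chart. Includes a seeded synthetic cohort generator emulating the episode
    structure of hospital administrative data so the whole pipeline is
    testable without access to patient-level records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
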