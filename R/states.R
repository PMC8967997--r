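#' Clinical states of the daily composite outcome
#'
#' Every patient-day of follow-up is assigned exactly one state from a fixed,
#' mutually exclusive list describing vital status and location: dead, in
#' hospital (index stay or readmission), in the emergency department (index
#' visit or revisit), at the day hospital, at an outpatient visit, or at home.
#' The vector is ordered by priority: when several situations apply on the
#' same calendar day (e.g. an ED arrival followed by a same-day admission),
#' the highest-priority state wins.
#'
#' @return Character vector of the eight state labels, highest priority first.
#' @export
#' @examples
#' clinical_states()
clinical_states <- function() {
  c("DEAD",
    "IN_HOSPITAL_INDEX",
    "IN_HOSPITAL_READMISSION",
    "IN_ED_INDEX",
    "IN_ED_REVISIT",
    "DAY_HOSPITAL",
    "OUTPATIENT_VISIT",
    "AT_HOME")
}

#' Episode kinds recognised by the data model
#' @return Character vector of valid `kind` values.
#' @export
episode_kinds <- function() {
  c("ED", "HOSPITALIZATION", "DAY_HOSPITAL", "OUTPATIENT")
}

#' Episode dispositions recognised by the data model
#' @return Character vector of valid `disposition` values.
#' @export
dispositions <- function() {
  c("HOME", "ADMITTED", "DIED", "OTHER")
}

#' Cost item categories of the full-costing system
#'
#' Every euro booked to an episode falls in one of three buckets: costs
#' directly imputable to the patient or episode (`DIRECT`), priced catalog
#' products and activities (`CATALOG`, carrying a quantity and unit cost),
#' and indirectly imputed residual costs (`RESIDUAL`).
#'
#' @return Character vector of valid `category` values.
#' @export
cost_categories <- function() {
  c("DIRECT", "CATALOG", "RESIDUAL")
}

# priority rank of a state vector: 1 = highest (DEAD)
state_rank <- function(state) {
  match(state, clinical_states())
}
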