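{
  "encoding": "UTF-8",
  "delimiter": ",",
  "decimal_mark": ".",
  "date_format": "YYYY-MM-DD",
  "tables": {
    "episodes.csv": {
      "columns": {
        "patient_id": "opaque identifier",
        "episode_id": "opaque identifier, unique",
        "kind": "ED | HOSPITALIZATION | DAY_HOSPITAL | OUTPATIENT",
        "start_date": "ISO date; first calendar date of the episode",
        "end_date": "ISO date; >= start_date; equals start_date for OUTPATIENT and DAY_HOSPITAL",
        "department": "free-text department label",
        "disposition": "HOME | ADMITTED | DIED | OTHER",
        "diagnoses": "pipe-separated system:code:position:poa fragments; system in {ICD10CM, ICPC2}; position 1 = principal, empty if undefined; poa Y/N, empty if not applicable; ICPC2 only on ED episodes"
      },
      "notes": "intervals are closed calendar-date pairs at the file level; hospital-day (half-open) conventions are applied by the analysis engine, not the format"
    },
    "vitals.csv": {
      "columns": {
        "patient_id": "opaque identifier, unique (at most one record per patient)",
        "death_date": "ISO date or empty when alive at end of registry follow-up"
      }
    },
    "costs.csv": {
      "columns": {
        "episode_id": "episode the line item is booked to",
        "category": "DIRECT | CATALOG | RESIDUAL",
        "description": "free text",
        "quantity": "non-negative count, CATALOG only, else empty",
        "unit_cost": "euros, CATALOG only, else empty",
        "amount": "euros, >= 0; for CATALOG equals quantity * unit_cost"
      },
      "notes": "amounts carry cent precision"
    }
  }
}
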