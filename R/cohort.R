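#' @title Cohort construction: heart-failure classification and strata
#' @description
#' Inclusion is anchored on emergency-department (ED) activity in a target
#' calendar year. A patient qualifies through either an ED heart-failure
#' code (ICPC-2 `K77`) or, for patients admitted from the ED without an HF
#' code there, an ICD-10-CM HF diagnosis on the linked hospitalization that
#' was present on admission (POA). Patients are classified as primary HF
#' (HF in the principal diagnosis position) or secondary HF (HF coded in a
#' non-principal position), and partitioned into three disposition arms:
#' hospitalized, discharged home from the ED, or died in the ED.
#' @name cohort_builder
NULL

hf_icd10_prefixes <- c("I110", "I130", "I132", "I50")

#' Does a diagnosis code denote heart failure?
#'
#' ICD-10-CM codes match if they fall under `I11.0`, `I13.0`, `I13.2` or
#' `I50` (any subcode); the ED (ICPC-2) heart-failure code is `K77`. Codes
#' are normalised before matching: dots are stripped and letters upper-cased,
#' so both the dotted (`I11.0`) and dotless (`I110`) dialects are accepted.
#'
#' @param system Coding system, `"ICD10CM"` or `"ICPC2"` (vectorised).
#' @param code Code string (vectorised).
#' @return Logical vector.
#' @export
#' @examples
#' match_hf_code("ICD10CM", "I50.9")   # TRUE
#' match_hf_code("ICD10CM", "I13.10")  # FALSE: I13.1 is not an HF category
#' match_hf_code("ICPC2", "K77")       # TRUE
match_hf_code <- function(system, code) {
  stopifnot(length(system) == length(code))
  norm <- toupper(gsub(".", "", code, fixed = TRUE))
  icd <- system == "ICD10CM" &
    Reduce(`|`, lapply(hf_icd10_prefixes, function(p) startsWith(norm, p)))
  icd | (system == "ICPC2" & norm == "K77")
}

#' Classify one episode's heart-failure status
#'
#' Applies the diagnosis-position rules to a single episode:
#'
#' * `PRIMARY_HF` — an HF code in position 1 (for hospitalizations it must
#'   additionally be flagged present on admission);
#' * `SECONDARY_HF` — no HF in position 1 but an HF code at a later position
#'   (hospitalizations: POA required);
#' * `EXCLUDED_NEW_ONSET` — a hospitalization whose only HF codes are not
#'   present on admission (HF that first appeared during the stay);
#' * `UNCLASSIFIABLE` — an ED `K77` whose diagnosis rank is undefined, so
#'   primary vs. secondary cannot be established;
#' * `NO_HF` — no HF code at all.
#'
#' @param kind Episode kind (`"ED"`, `"HOSPITALIZATION"`, ...).
#' @param diagnoses Data frame as returned by [parse_diagnoses()]; must have
#'   at least one row.
#' @return One of `"PRIMARY_HF"`, `"SECONDARY_HF"`, `"NO_HF"`,
#'   `"UNCLASSIFIABLE"`, `"EXCLUDED_NEW_ONSET"`.
#' @export
classify_episode <- function(kind, diagnoses) {
  stopifnot(kind %in% episode_kinds())
  if (!is.data.frame(diagnoses) || nrow(diagnoses) == 0L)
    stop("classify_episode() requires at least one diagnosis")
  hf <- match_hf_code(diagnoses$system, diagnoses$code)
  if (!any(hf)) return("NO_HF")
  usable <- hf
  if (kind == "HOSPITALIZATION") {
    # only codes present on admission count; HF arising de novo in-stay is
    # a new-onset diagnosis and excludes the episode
    usable <- hf & !is.na(diagnoses$poa) & diagnoses$poa
    if (!any(usable)) return("EXCLUDED_NEW_ONSET")
  }
  if (any(usable & is.na(diagnoses$position)) &&
      !any(usable & !is.na(diagnoses$position)))
    return("UNCLASSIFIABLE")
  pos <- diagnoses$position[usable & !is.na(diagnoses$position)]
  if (any(pos == 1L)) "PRIMARY_HF" else "SECONDARY_HF"
}

# Link each ED episode (disposition ADMITTED) to the hospitalization that
# starts on, or within `window` days after, the ED end date.
link_admissions <- function(episodes, window = 1L) {
  ed <- episodes[episodes$kind == "ED" & episodes$disposition == "ADMITTED", ]
  hosp <- episodes[episodes$kind == "HOSPITALIZATION", ]
  hosp_by_pt <- split(seq_len(nrow(hosp)), hosp$patient_id)
  pt_slot <- match(ed$patient_id, names(hosp_by_pt))
  out <- rep(NA_character_, nrow(ed))
  for (i in seq_len(nrow(ed))) {
    if (is.na(pt_slot[i])) next
    j <- hosp_by_pt[[pt_slot[i]]]
    ok <- j[hosp$start_date[j] >= ed$end_date[i] &
              hosp$start_date[j] <= ed$end_date[i] + window]
    if (length(ok))
      out[i] <- hosp$episode_id[ok[order(hosp$start_date[ok])][1L]]
  }
  stats::setNames(out, ed$episode_id)
}

check_no_overlapping_hospitalizations <- function(episodes) {
  hosp <- episodes[episodes$kind == "HOSPITALIZATION", ]
  for (h in split(hosp, hosp$patient_id)) {
    pid <- h$patient_id[1]
    h <- h[order(h$start_date, h$end_date), ]
    if (nrow(h) > 1L) {
      # stays are half-open [start, end): touching at the boundary is fine
      prev_end <- h$end_date[-nrow(h)]
      next_start <- h$start_date[-1L]
      bad <- next_start < prev_end
      if (any(bad))
        stop("overlapping hospitalizations for patient ", pid, ": ",
             paste(unique(c(h$episode_id[c(bad, FALSE)],
                            h$episode_id[c(FALSE, bad)])), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Build the analysis strata for a calendar year
#'
#' Finds each patient's index episode — the first ED visit of the year that
#' carries an HF classification either on the visit itself or on its linked
#' hospitalization — and partitions included patients into the 3 x 2 strata
#' of disposition arm (`HOSPITALIZED`, `DISCHARGED_HOME_FROM_ED`,
#' `DIED_IN_ED`) by HF group (`pHF`, `sHF`). Patients whose first qualifying
#' classification is `UNCLASSIFIABLE` or `EXCLUDED_NEW_ONSET` are listed in
#' the `excluded` attribute with per-reason counts rather than stratified.
#'
#' @param episodes Episode table ([read_episodes()] layout).
#' @param vitals Vital-status table.
#' @param year Target calendar year, e.g. `2018`.
#' @param linkage_window Days after the ED end date within which an
#'   admission is considered the same care contact (default 1, covering
#'   midnight-crossing admissions).
#' @return Data frame of class `"cohort_strata"`, one row per included
#'   patient: `patient_id`, `arm`, `hf_group`, `index_episode_id` (the index
#'   ED visit), `index_hosp_id` (linked hospitalization or `NA`),
#'   `index_admission_date` (ED arrival), `index_discharge_date` (hospital
#'   discharge for the hospitalized arm, ED end otherwise, `NA` for ED
#'   deaths). Attribute `excluded`: data frame of excluded patients and
#'   reasons.
#' @export
build_strata <- function(episodes, vitals, year, linkage_window = 1L) {
  stopifnot(is.data.frame(episodes), is.data.frame(vitals))
  episodes$start_date <- as.Date(episodes$start_date)
  episodes$end_date <- as.Date(episodes$end_date)
  check_no_overlapping_hospitalizations(episodes)
  links <- link_admissions(episodes, linkage_window)

  ed <- episodes[episodes$kind == "ED" &
                   format(episodes$start_date, "%Y") == as.character(year), ]
  ed <- ed[order(ed$patient_id, ed$start_date, ed$episode_id), ]

  hosp_lookup <- match(links, episodes$episode_id)
  names(hosp_lookup) <- names(links)
  acc <- list(patient_id = character(), arm = character(),
              hf_group = character(), index_episode_id = character(),
              index_hosp_id = character(), index_admission_date = numeric(),
              index_discharge_date = numeric())
  ex <- list(patient_id = character(), reason = character(),
             index_episode_id = character())
  for (visits in split(ed, ed$patient_id)) {
    pid <- visits$patient_id[1]
    for (i in seq_len(nrow(visits))) {
      cls <- classify_episode("ED", parse_diagnoses(visits$diagnoses[i]))
      vid <- visits$episode_id[i]
      hosp_id <- unname(links[vid])
      hosp_row <- unname(hosp_lookup[vid])
      if (cls == "NO_HF" && !is.na(hosp_id)) {
        hd <- parse_diagnoses(episodes$diagnoses[hosp_row])
        if (nrow(hd)) cls <- classify_episode("HOSPITALIZATION", hd)
      }
      if (cls == "NO_HF") next
      if (cls %in% c("UNCLASSIFIABLE", "EXCLUDED_NEW_ONSET")) {
        ex$patient_id <- c(ex$patient_id, pid)
        ex$reason <- c(ex$reason, cls)
        ex$index_episode_id <- c(ex$index_episode_id, vid)
      } else {
        arm <- if (visits$disposition[i] == "DIED") {
          "DIED_IN_ED"
        } else if (!is.na(hosp_id)) {
          "HOSPITALIZED"
        } else {
          "DISCHARGED_HOME_FROM_ED"
        }
        discharge <- switch(arm,
          HOSPITALIZED = as.numeric(episodes$end_date[hosp_row]),
          DISCHARGED_HOME_FROM_ED = as.numeric(visits$end_date[i]),
          DIED_IN_ED = NA_real_)
        acc$patient_id <- c(acc$patient_id, pid)
        acc$arm <- c(acc$arm, arm)
        acc$hf_group <- c(acc$hf_group,
                          if (cls == "PRIMARY_HF") "pHF" else "sHF")
        acc$index_episode_id <- c(acc$index_episode_id, vid)
        acc$index_hosp_id <- c(acc$index_hosp_id, hosp_id)
        acc$index_admission_date <- c(acc$index_admission_date,
                                      as.numeric(visits$start_date[i]))
        acc$index_discharge_date <- c(acc$index_discharge_date, discharge)
      }
      break  # first qualifying visit anchors the patient
    }
  }
  out <- as.data.frame(acc, stringsAsFactors = FALSE)
  out$index_admission_date <- as.Date(out$index_admission_date,
                                      origin = "1970-01-01")
  out$index_discharge_date <- as.Date(out$index_discharge_date,
                                      origin = "1970-01-01")
  excluded <- as.data.frame(ex, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "excluded_counts") <- table(excluded$reason)
  class(out) <- c("cohort_strata", class(out))
  out
}

#' @export
print.cohort_strata <- function(x, ...) {
  cat("Cohort strata:", nrow(x), "included patients\n")
  if (nrow(x)) print(table(arm = x$arm, hf_group = x$hf_group))
  ex <- attr(x, "excluded")
  if (nrow(ex)) {
    cat("Excluded:\n")
    print(table(ex$reason))
  }
  invisible(x)
}
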