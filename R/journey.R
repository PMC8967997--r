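#' @title The daily clinical-state engine
#' @description
#' The composite-outcome model reduces each patient's follow-up to one
#' clinical state per day. Day 0 is the index ED arrival and the timeline
#' runs for a fixed horizon (30 or 365 days), so a cohort of n patients
#' contributes exactly n x horizon patient-days. A hospitalization occupies
#' the days from admission up to but excluding the discharge date (minimum
#' one day), matching the length-of-stay convention discharge minus
#' admission; ED, day-hospital and outpatient episodes occupy every calendar
#' date they touch. When several situations coincide on a day the fixed
#' priority order of [clinical_states()] decides (death always wins; a
#' same-day ED visit plus admission renders as hospital).
#' @name coherent_engine
NULL

#' Assemble one patient's journey
#'
#' @param patient_id Patient identifier.
#' @param episodes Episode table (all patients or just this one).
#' @param vitals Vital-status table.
#' @param anchor_date Day 0 of the timeline (index ED arrival).
#' @param horizon Follow-up length in days (30 or 365).
#' @param index_episode_ids Episode ids forming the index care contact (the
#'   index ED visit and, if admitted, its linked hospitalization). Episodes
#'   not in this set count as revisits/readmissions.
#' @return Object of class `"patient_journey"`: the patient's episodes
#'   clipped to `[anchor, anchor + horizon)`, sorted by start date, plus
#'   `death_day` (integer day index; `NA` if no death recorded, `Inf` if the
#'   death falls beyond the horizon).
#' @export
patient_journey <- function(patient_id, episodes, vitals, anchor_date,
                            horizon = 365L, index_episode_ids = character()) {
  stopifnot(horizon > 0)
  anchor <- as.Date(anchor_date)
  ep <- episodes[episodes$patient_id == patient_id, , drop = FALSE]
  ep$start_date <- as.Date(ep$start_date)
  ep$end_date <- as.Date(ep$end_date)
  keep <- ep$start_date < anchor + horizon & ep$end_date >= anchor
  ep <- ep[keep, , drop = FALSE]
  ep <- ep[order(ep$start_date, ep$episode_id), , drop = FALSE]
  dd <- vitals$death_date[match(patient_id, vitals$patient_id)]
  death_day <- if (length(dd) == 0L || is.na(dd)) NA_real_ else {
    d <- as.numeric(as.Date(dd) - anchor)
    if (d >= horizon) Inf else d
  }
  structure(list(patient_id = patient_id, anchor = anchor,
                 horizon = as.integer(horizon), episodes = ep,
                 death_day = death_day,
                 index_episode_ids = index_episode_ids),
            class = "patient_journey")
}

#' Journeys for every patient of a stratified cohort
#'
#' Convenience constructor: one [patient_journey()] per row of `strata`,
#' anchored at each patient's index admission date. Patients who died in the
#' ED have no follow-up and are skipped.
#'
#' @param strata A `"cohort_strata"` object from [build_strata()].
#' @param episodes,vitals Record tables.
#' @param horizon Follow-up days.
#' @return Named list of `"patient_journey"` objects.
#' @export
cohort_journeys <- function(strata, episodes, vitals, horizon = 365L) {
  keep <- strata$arm != "DIED_IN_ED"
  s <- strata[keep, , drop = FALSE]
  ep_by_pt <- split(episodes, episodes$patient_id)
  empty_ep <- episodes[0, , drop = FALSE]
  out <- lapply(seq_len(nrow(s)), function(i) {
    patient_journey(
      s$patient_id[i], ep_by_pt[[s$patient_id[i]]] %||% empty_ep, vitals,
      anchor_date = s$index_admission_date[i], horizon = horizon,
      index_episode_ids = stats::na.omit(c(s$index_episode_id[i],
                                           s$index_hosp_id[i])))
  })
  stats::setNames(out, s$patient_id)
}

# day indices (0-based) occupied by one episode row, unclipped
episode_days <- function(kind, start, end, anchor) {
  s <- as.numeric(as.Date(start) - anchor)
  e <- as.numeric(as.Date(end) - anchor)
  if (kind == "HOSPITALIZATION") {
    # half-open [admission, discharge), but a same-day stay still occupies
    # its admission day
    seq.int(s, max(s, e - 1))
  } else {
    seq.int(s, e)
  }
}

#' Assign the daily state sequence of one journey
#'
#' @param journey A `"patient_journey"`.
#' @return Factor vector of length `horizon` with levels
#'   `clinical_states()`; element d+1 is the state on day d.
#' @export
#' @examples
#' eps <- data.frame(patient_id = "p1", episode_id = "e1", kind = "ED",
#'                   start_date = as.Date("2018-02-01"),
#'                   end_date = as.Date("2018-02-02"),
#'                   department = "ED", disposition = "HOME", diagnoses = "")
#' vit <- data.frame(patient_id = "p1", death_date = as.Date("2018-02-11"))
#' j <- patient_journey("p1", eps, vit, "2018-02-01", horizon = 30,
#'                      index_episode_ids = "e1")
#' table(assign_daily_states(j))
assign_daily_states <- function(journey) {
  stopifnot(inherits(journey, "patient_journey"))
  h <- journey$horizon
  states <- clinical_states()
  out <- rep("AT_HOME", h)
  ep <- journey$episodes
  if (nrow(ep)) {
    state_of <- function(kind, id) {
      is_index <- id %in% journey$index_episode_ids
      switch(kind,
        HOSPITALIZATION = if (is_index) "IN_HOSPITAL_INDEX"
                          else "IN_HOSPITAL_READMISSION",
        ED = if (is_index) "IN_ED_INDEX" else "IN_ED_REVISIT",
        DAY_HOSPITAL = "DAY_HOSPITAL",
        OUTPATIENT = "OUTPATIENT_VISIT")
    }
    # paint lowest-priority states first; higher priorities overwrite
    ord <- order(-state_rank(vapply(seq_len(nrow(ep)), function(i)
      state_of(ep$kind[i], ep$episode_id[i]), "")))
    for (i in ord) {
      st <- state_of(ep$kind[i], ep$episode_id[i])
      d <- episode_days(ep$kind[i], ep$start_date[i], ep$end_date[i],
                        journey$anchor)
      d <- d[d >= 0 & d < h]
      out[d + 1] <- st
    }
  }
  if (!is.na(journey$death_day) && is.finite(journey$death_day) &&
      journey$death_day < h) {
    dd <- max(0, journey$death_day)
    out[seq.int(dd, h - 1) + 1] <- "DEAD"
  }
  factor(out, levels = states)
}

#' Cohort occupancy matrix
#'
#' Fraction of the cohort in each clinical state on each day of follow-up:
#' the numeric layer behind the stacked-area composite-outcome chart. Every
#' day-column sums to 1 and the `DEAD` fraction is non-decreasing.
#'
#' @param journeys Non-empty list of `"patient_journey"` objects sharing one
#'   horizon.
#' @return Object of class `"daily_state_matrix"`: a `horizon x 8` numeric
#'   matrix of fractions (rows = days, columns = states), with attribute
#'   `n` (cohort size).
#' @export
occupancy <- function(journeys) {
  if (length(journeys) == 0L) stop("empty cohort")
  hs <- vapply(journeys, function(j) j$horizon, 1L)
  if (length(unique(hs)) != 1L)
    stop("all journeys must share one horizon")
  h <- hs[[1]]
  states <- clinical_states()
  counts <- matrix(0L, nrow = h, ncol = length(states),
                   dimnames = list(NULL, states))
  for (j in journeys) {
    idx <- cbind(seq_len(h), as.integer(assign_daily_states(j)))
    counts[idx] <- counts[idx] + 1L
  }
  m <- counts / length(journeys)
  structure(m, n = length(journeys), class = c("daily_state_matrix",
                                               class(m)))
}

#' @export
print.daily_state_matrix <- function(x, ...) {
  cat("Daily state occupancy:", nrow(x), "days x", ncol(x), "states, n =",
      attr(x, "n"), "patients\n")
  print(utils::head(unclass(x), 5))
  invisible(x)
}

#' Summarise one journey's day counts
#'
#' Day totals per state category over the horizon, plus the share of time
#' alive and out of hospital that was spent at home:
#' `days_at_home / (horizon - days_dead - days_in_hospital)`, defined as 1
#' when the denominator is zero (e.g. death on day 0).
#'
#' @param journey A `"patient_journey"`.
#' @return One-row data frame: `days_at_home`, `days_in_hospital`,
#'   `days_with_ED_visit`, `days_in_day_hospital`,
#'   `days_with_outpatient_visit`, `days_dead`,
#'   `pct_home_of_alive_out_of_hospital`. Day counts sum to the horizon.
#' @export
summarize_journey <- function(journey) {
  st <- assign_daily_states(journey)
  n <- table(st)
  hosp <- sum(n[c("IN_HOSPITAL_INDEX", "IN_HOSPITAL_READMISSION")])
  ed <- sum(n[c("IN_ED_INDEX", "IN_ED_REVISIT")])
  home <- as.integer(n["AT_HOME"])
  dead <- as.integer(n["DEAD"])
  denom <- journey$horizon - dead - hosp
  data.frame(
    days_at_home = home,
    days_in_hospital = as.integer(hosp),
    days_with_ED_visit = as.integer(ed),
    days_in_day_hospital = as.integer(n["DAY_HOSPITAL"]),
    days_with_outpatient_visit = as.integer(n["OUTPATIENT_VISIT"]),
    days_dead = dead,
    pct_home_of_alive_out_of_hospital = if (denom == 0) 1 else home / denom)
}

#' Length of stay of an ED or hospital episode
#'
#' Hospital stays count discharge date minus admission date in whole days
#' (a same-day discharge is 0). ED stays count the number of calendar dates
#' touched (a same-day visit is 1), which is the scale on which mean ED
#' stays of about 1.7 days arise.
#'
#' @param kind `"HOSPITALIZATION"` or `"ED"`.
#' @param start_date,end_date Episode dates.
#' @return Integer days (vectorised).
#' @export
length_of_stay <- function(kind, start_date, end_date) {
  if (!all(kind %in% c("HOSPITALIZATION", "ED")))
    stop("length_of_stay() is defined for HOSPITALIZATION and ED episodes")
  d <- as.numeric(as.Date(end_date) - as.Date(start_date))
  if (any(d < 0)) stop("end_date before start_date")
  kind <- rep_len(kind, length(d))
  as.integer(ifelse(kind == "HOSPITALIZATION", d, d + 1))
}
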