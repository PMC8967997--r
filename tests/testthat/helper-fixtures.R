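# Shared fixture builders. Everything is generated in code; no files ship
# with the tests.

make_episode <- function(patient_id, episode_id, kind, start, end = start,
                         department = "ED", disposition = "HOME",
                         diagnoses = "") {
  data.frame(patient_id = patient_id, episode_id = episode_id, kind = kind,
             start_date = as.Date(start), end_date = as.Date(end),
             department = department, disposition = disposition,
             diagnoses = diagnoses)
}

bind_episodes <- function(...) do.call(rbind, list(...))

no_vitals <- function() {
  data.frame(patient_id = character(), death_date = as.Date(character()))
}

vitals_of <- function(patient_id, death_date = as.Date(NA)) {
  data.frame(patient_id = patient_id, death_date = as.Date(death_date))
}

# a small synthetic cohort shared by several test files
small_params <- function(n_hosp = 60L, n_home = 25L, n_died = 2L) {
  p <- synthetic_params()
  for (g in names(p$groups)) {
    p$groups[[g]]$hospitalized$n <- n_hosp
    p$groups[[g]]$ed_home$n <- n_home
    p$groups[[g]]$died_in_ed$n <- n_died
  }
  p
}

small_cohort <- function(seed = 101, ...) {
  generate_cohort(small_params(...), seed = seed)
}

# independent day-by-day membership oracle for the state engine: scans the
# raw episode rows for every single day, never reusing the engine's interval
# logic
oracle_states <- function(journey) {
  h <- journey$horizon
  ep <- journey$episodes
  out <- character(h)
  for (d in seq_len(h) - 1L) {
    date <- journey$anchor + d
    if (!is.na(journey$death_day) && is.finite(journey$death_day) &&
        d >= journey$death_day) {
      out[d + 1] <- "DEAD"
      next
    }
    st <- "AT_HOME"
    best <- function(cand) {
      if (match(cand, clinical_states()) < match(st, clinical_states()))
        st <<- cand
    }
    for (i in seq_len(nrow(ep))) {
      s <- ep$start_date[i]; e <- ep$end_date[i]
      covered <- switch(ep$kind[i],
        HOSPITALIZATION = (date >= s && date < e) || (s == e && date == s),
        date >= s && date <= e)
      if (!covered) next
      idx <- ep$episode_id[i] %in% journey$index_episode_ids
      best(switch(ep$kind[i],
        HOSPITALIZATION = if (idx) "IN_HOSPITAL_INDEX"
                          else "IN_HOSPITAL_READMISSION",
        ED = if (idx) "IN_ED_INDEX" else "IN_ED_REVISIT",
        DAY_HOSPITAL = "DAY_HOSPITAL",
        OUTPATIENT = "OUTPATIENT_VISIT"))
    }
    out[d + 1] <- st
  }
  factor(out, levels = clinical_states())
}

# random journeys for property tests: direct construction, independent of
# the synthetic generator
random_journey <- function(pid, horizon = 365L) {
  anchor <- as.Date("2018-01-01") + sample.int(300, 1)
  n_ep <- sample(0:6, 1)
  eps <- list()
  for (k in seq_len(n_ep)) {
    kind <- sample(episode_kinds(), 1)
    start <- anchor + sample.int(horizon, 1) - 1L
    end <- if (kind == "HOSPITALIZATION") start + sample(0:15, 1) else
      if (kind == "ED") start + sample(0:2, 1) else start
    eps[[k]] <- make_episode(pid, sprintf("%s-%d", pid, k), kind, start, end)
  }
  eps <- if (length(eps)) do.call(rbind, eps) else
    make_episode(pid, "none", "ED", anchor)[0, ]
  death <- if (stats::runif(1) < 0.3)
    anchor + sample.int(horizon + 100, 1) else as.Date(NA)
  patient_journey(pid, eps, vitals_of(pid, death), anchor, horizon,
                  index_episode_ids = if (nrow(eps)) eps$episode_id[1]
                                      else character())
}
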