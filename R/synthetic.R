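#' @title Seeded synthetic cohort generator
#' @description
#' Emulates the episode structure of a hospital's administrative records for
#' a heart-failure cohort: an index ED visit (with a linked hospitalization
#' for the hospitalized arm) carrying planted primary/secondary HF codes,
#' death times from a two-piece constant hazard matched to the 30-day and
#' 1-year cumulative mortality, post-discharge readmission and ED-revisit
#' point processes stopped at death, overdispersed outpatient activity, and
#' log-normal episode costs split into direct/catalog/residual line items at
#' cent precision. Default parameters are the published aggregates of the
#' reference cohort (see [reference_cost_aggregates()]); ground-truth labels
#' are emitted alongside the tables so classification can be verified
#' exactly.
#' @name synthetic_cohort
NULL

#' Default generator parameters
#'
#' One block per HF group (`pHF`, `sHF`) and disposition arm. Rates are
#' cumulative probabilities (30-day rates anchored at index discharge),
#' length of stay is log-normal matched to median 8 (IQR 6-12) days, visit
#' counts are negative-binomial (outpatient) or Poisson (day hospital), and
#' episode costs are log-normal with the per-kind means/SDs of the reference
#' aggregates. `ed_days_probs` is the distribution of calendar dates touched
#' by an ED visit (mean 1.66 days).
#'
#' @return Object of class `"synthetic_params"` (nested list).
#' @export
synthetic_params <- function() {
  los <- list(median = 8, iqr = c(6, 12))
  p <- list(
    year = 2018L,
    ed_days_probs = c(`1` = 0.44, `2` = 0.46, `3` = 0.10),
    groups = list(
      pHF = list(
        hospitalized = list(
          n = 1029L, p_inhosp_death = 0.064, p_death_30d = 0.067,
          p_death_1y = 0.258, los = los,
          p_readm_30d = 0.134, p_readm_1y = 0.474,
          p_re_ed_30d = 0.168, p_re_ed_1y = 0.614,
          outpatient_mean = 12.6, outpatient_sd = 11.1,
          day_hospital_mean = 427 / 1029,
          p_hf_not_in_ed = 134 / 1029,
          costs = list(ED = c(343.2, 141.8), DAY_HOSPITAL = c(543.4, 944.9),
                       INDEX_HOSP = c(3907.7, 6323.2),
                       READMISSION = c(4465.1, 7057.2))),
        ed_home = list(
          n = 434L, p_death_30d = 0.018, p_death_1y = 0.166,
          p_hosp_30d = 0.118, p_hosp_1y = 0.509,
          p_re_ed_30d = 0.242, p_re_ed_1y = 0.739,
          outpatient_mean = 12.6, outpatient_sd = 11.1,
          day_hospital_mean = 0.2, los = los,
          costs = list(ED = c(343.2, 141.8), DAY_HOSPITAL = c(543.4, 944.9),
                       INDEX_HOSP = c(3907.7, 6323.2),
                       READMISSION = c(4465.1, 7057.2))),
        died_in_ed = list(n = 8L)),
      sHF = list(
        hospitalized = list(
          n = 1257L, p_inhosp_death = 0.109, p_death_30d = 0.121,
          p_death_1y = 0.32, los = los,
          p_readm_30d = 0.133, p_readm_1y = 0.436,
          p_re_ed_30d = 0.156, p_re_ed_1y = 0.564,
          outpatient_mean = 11.4, outpatient_sd = 11.7,
          day_hospital_mean = 812 / 1257,
          p_hf_not_in_ed = 589 / 1257,
          costs = list(ED = c(343.5, 141.7), DAY_HOSPITAL = c(737.5, 1298.1),
                       INDEX_HOSP = c(4656.1, 6532.3),
                       READMISSION = c(4700.6, 7440.7))),
        ed_home = list(
          n = 363L, p_death_30d = 0.033, p_death_1y = 0.204,
          p_hosp_30d = 0.088, p_hosp_1y = 0.407,
          p_re_ed_30d = 0.212, p_re_ed_1y = 0.652,
          outpatient_mean = 11.4, outpatient_sd = 11.7,
          day_hospital_mean = 0.2, los = los,
          costs = list(ED = c(343.5, 141.7), DAY_HOSPITAL = c(737.5, 1298.1),
                       INDEX_HOSP = c(4656.1, 6532.3),
                       READMISSION = c(4700.6, 7440.7))),
        died_in_ed = list(n = 7L))))
  class(p) <- "synthetic_params"
  p
}

# two-piece constant hazard matched to cumulative probabilities at t1, t2
two_piece_hazard <- function(p_t1, p_t2, t1 = 30, t2 = 365) {
  if (p_t1 < 0 || p_t2 > 0.999999 || p_t1 > p_t2)
    stop("infeasible probability ordering: need 0 <= p(", t1, ") <= p(",
         t2, ") < 1")
  list(h1 = -log(1 - p_t1) / t1,
       h2 = (log(1 - p_t1) - log(1 - p_t2)) / (t2 - t1),
       t1 = t1, t2 = t2)
}

# sample a first-event time from a two-piece exponential; Inf if no event
# within [0, t2]
r_two_piece <- function(n, hz) {
  u <- stats::runif(n)
  cum1 <- hz$h1 * hz$t1
  t <- ifelse(-log(1 - u) <= cum1,
              -log(1 - u) / hz$h1,
              hz$t1 + (-log(1 - u) - cum1) / hz$h2)
  ifelse(t > hz$t2, Inf, t)
}

r_los <- function(n, los) {
  q <- lnorm_from_quartiles(los$median, los$iqr[1], los$iqr[2])
  pmax(1L, as.integer(round(stats::rlnorm(n, q$meanlog, q$sdlog))))
}

r_cost <- function(n, ms) {
  m <- lnorm_from_moments(ms[1], ms[2])
  round(stats::rlnorm(n, m$meanlog, m$sdlog), 2)
}

r_count_nb <- function(n, mean, sd) {
  if (sd^2 <= mean) return(stats::rpois(n, mean))
  stats::rnbinom(n, size = mean^2 / (sd^2 - mean), mu = mean)
}

# cost line items for one episode: direct / catalog / residual at cent
# precision, catalog satisfying amount = quantity * unit_cost exactly
make_cost_items <- function(total) {
  parts <- split_amount(total, c(0.5, 0.3, 0.2))
  q <- sample(1:4, 1)
  unit <- round(parts[2] / q, 2)
  catalog <- round(q * unit, 2)
  direct <- round(total - catalog - parts[3], 2)
  if (direct < 0) { # tiny totals: fold everything into one direct item
    return(list(cat = "DIRECT", desc = "ward care", q = NA_real_,
                unit = NA_real_, amt = round(total, 2)))
  }
  list(cat = c("DIRECT", "CATALOG", "RESIDUAL"),
       desc = c("ward care", "catalog services", "imputed residual"),
       q = c(NA, q, NA), unit = c(NA, unit, NA),
       amt = c(direct, catalog, parts[3]))
}

hf_primary_hosp_dx <- "ICD10CM:I50.9:1:Y|ICD10CM:N17.9:2:Y"
hf_secondary_hosp_dx <- "ICD10CM:J18.9:1:Y|ICD10CM:I50.9:2:Y"
nonhf_hosp_dx <- "ICD10CM:J18.9:1:Y"
ed_primary_dx <- "ICPC2:K77:1:"
ed_secondary_dx <- "ICPC2:R02:1:|ICPC2:K77:2:"
ed_nonhf_dx <- "ICPC2:R02:1:"

#' Generate a synthetic cohort
#'
#' Produces the three record tables (`episodes`, `vitals`, `costs`) plus a
#' `truth` sidecar with each patient's planted HF group, arm and index
#' episode ids. Each patient is drawn from an independent RNG substream
#' derived from `seed` and the patient's index, so output is byte-identical
#' for a fixed seed and earlier patients are unaffected when `n` grows.
#'
#' @param params A `"synthetic_params"` object; see [synthetic_params()].
#' @param seed Integer seed driving all randomness.
#' @return Object of class `"synthetic_cohort"`: list of data frames
#'   `episodes`, `vitals`, `costs`, `truth`.
#' @export
#' @examples
#' p <- synthetic_params()
#' p$groups$pHF$hospitalized$n <- 20L
#' p$groups$pHF$ed_home$n <- 5L
#' p$groups$sHF$hospitalized$n <- 20L
#' p$groups$sHF$ed_home$n <- 5L
#' coh <- generate_cohort(p, seed = 1)
#' head(coh$episodes)
generate_cohort <- function(params, seed) {
  stopifnot(inherits(params, "synthetic_params"), is.numeric(seed))
  year0 <- as.Date(sprintf("%d-01-01", params$year))
  eps <- list(); vit <- list(); cst <- list(); tru <- list()
  idx <- 0L
  for (g in names(params$groups)) {
    for (arm in c("hospitalized", "ed_home", "died_in_ed")) {
      block <- params$groups[[g]][[arm]]
      if (is.null(block) || block$n < 1L) next
      for (k in seq_len(block$n)) {
        idx <- idx + 1L
        set.seed(substream_seed(seed, idx))
        pt <- simulate_patient(sprintf("P%06d", idx), g, arm, block,
                               params, year0)
        eps[[idx]] <- pt$episodes
        vit[[idx]] <- pt$vital
        cst[[idx]] <- pt$costs
        tru[[idx]] <- pt$truth
      }
    }
  }
  bind_chunks <- function(chunks) {
    chunks <- chunks[!vapply(chunks, is.null, TRUE)]
    cols <- names(chunks[[1]])
    out <- lapply(cols, function(cn)
      do.call(c, lapply(chunks, `[[`, cn)))
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  episodes <- bind_chunks(eps)
  episodes$start_date <- as.Date(episodes$start_date,
                                 origin = "1970-01-01")
  episodes$end_date <- as.Date(episodes$end_date, origin = "1970-01-01")
  vitals <- bind_chunks(vit)
  vitals$death_date <- as.Date(vitals$death_date, origin = "1970-01-01")
  out <- list(episodes = episodes, vitals = vitals,
              costs = bind_chunks(cst), truth = bind_chunks(tru))
  class(out) <- "synthetic_cohort"
  out
}

# one patient's episodes, vital record, cost items and truth row; episodes
# and costs are returned as column lists (dates numeric, days since epoch)
# and bound into data frames once per cohort for speed
simulate_patient <- function(pid, g, arm, block, params, year0) {
  e <- list(id = character(), kind = character(), start = numeric(),
            end = numeric(), dept = character(), disp = character(),
            dx = character())
  cs <- list(eid = character(), cat = character(), desc = character(),
             q = numeric(), unit = numeric(), amt = numeric())
  eid <- 0L
  new_eid <- function() {
    eid <<- eid + 1L
    sprintf("%s-E%02d", pid, eid)
  }
  add_episode <- function(kind, start, end, dept, disp, dx, cost_kind) {
    id <- new_eid()
    e$id <<- c(e$id, id)
    e$kind <<- c(e$kind, kind)
    e$start <<- c(e$start, as.numeric(start))
    e$end <<- c(e$end, as.numeric(end))
    e$dept <<- c(e$dept, dept)
    e$disp <<- c(e$disp, disp)
    e$dx <<- c(e$dx, dx)
    if (!is.null(cost_kind)) {
      it <- make_cost_items(r_cost(1, block$costs[[cost_kind]]))
      cs$eid <<- c(cs$eid, rep(id, length(it$cat)))
      cs$cat <<- c(cs$cat, it$cat)
      cs$desc <<- c(cs$desc, it$desc)
      cs$q <<- c(cs$q, it$q)
      cs$unit <<- c(cs$unit, it$unit)
      cs$amt <<- c(cs$amt, it$amt)
    }
    id
  }
  finish <- function(id_ed, index_hosp_id, death_date, arm_label) {
    list(
      episodes = list(patient_id = rep(pid, length(e$id)), episode_id = e$id,
                      kind = e$kind, start_date = e$start, end_date = e$end,
                      department = e$dept, disposition = e$disp,
                      diagnoses = e$dx),
      vital = list(patient_id = pid, death_date = as.numeric(death_date)),
      costs = if (length(cs$eid))
        list(episode_id = cs$eid, category = cs$cat, description = cs$desc,
             quantity = cs$q, unit_cost = cs$unit, amount = cs$amt),
      truth = list(patient_id = pid, hf_group = g, arm = arm_label,
                   index_episode_id = id_ed, index_hosp_id = index_hosp_id))
  }
  ed_days <- sample(as.integer(names(params$ed_days_probs)), 1,
                    prob = params$ed_days_probs)
  anchor <- year0 + sample.int(365L, 1L) - 1L
  ed_end <- anchor + (ed_days - 1L)
  death_date <- as.Date(NA)
  index_hosp_id <- NA_character_

  if (arm == "died_in_ed") {
    dx <- if (g == "pHF") ed_primary_dx else ed_secondary_dx
    id_ed <- add_episode("ED", anchor, ed_end, "ED", "DIED", dx, NULL)
    return(finish(id_ed, NA_character_, ed_end, "DIED_IN_ED"))
  }

  if (arm == "hospitalized") {
    hf_in_ed <- stats::runif(1) >= block$p_hf_not_in_ed
    ed_dx <- if (!hf_in_ed) ed_nonhf_dx
             else if (g == "pHF") ed_primary_dx else ed_secondary_dx
    hosp_dx <- if (g == "pHF") hf_primary_hosp_dx else hf_secondary_hosp_dx
    id_ed <- add_episode("ED", anchor, ed_end, "ED", "ADMITTED", ed_dx, "ED")
    los <- r_los(1, block$los)
    hosp_start <- ed_end
    hosp_end <- hosp_start + los
    died_in_hosp <- stats::runif(1) < block$p_inhosp_death
    dept <- sample(c("cardiology", "internal medicine", "ICU", "other"), 1,
                   prob = if (g == "pHF") c(0.22, 0.76, 0.01, 0.01)
                          else c(0.10, 0.84, 0.03, 0.03))
    index_hosp_id <- add_episode("HOSPITALIZATION", hosp_start, hosp_end,
                                 dept, if (died_in_hosp) "DIED" else "HOME",
                                 hosp_dx, "INDEX_HOSP")
    discharge <- hosp_end
    if (died_in_hosp) {
      death_date <- hosp_end
      death_post <- 0
    } else {
      q30 <- (block$p_death_30d - block$p_inhosp_death) /
        (1 - block$p_inhosp_death)
      q1y <- (block$p_death_1y - block$p_inhosp_death) /
        (1 - block$p_inhosp_death)
      death_post <- r_two_piece(1, two_piece_hazard(q30, q1y))
      if (is.finite(death_post)) {
        death_post <- max(1, ceiling(death_post))
        death_date <- discharge + death_post
      } else death_post <- Inf
    }
    if (!died_in_hosp) {
      q <- 1 - block$p_inhosp_death
      readm <- recurrent_stays(
        two_piece_hazard(block$p_readm_30d / q,
                         min(block$p_readm_1y / q, 0.999)),
        death_post, block$los)
      for (r in seq_len(nrow(readm))) {
        died_here <- is.finite(death_post) &&
          death_post <= readm$end[r] && death_post > readm$start[r]
        add_episode("HOSPITALIZATION", discharge + readm$start[r],
                    discharge + if (died_here) death_post else readm$end[r],
                    "internal medicine",
                    if (died_here) "DIED" else "HOME",
                    nonhf_hosp_dx, "READMISSION")
      }
      re_ed <- recurrent_points(
        two_piece_hazard(block$p_re_ed_30d / q,
                         min(block$p_re_ed_1y / q, 0.999)),
        death_post)
      for (t in re_ed)
        add_episode("ED", discharge + t, discharge + t, "ED", "HOME",
                    ed_nonhf_dx, "ED")
    }
  } else { # ed_home
    ed_dx <- if (g == "pHF") ed_primary_dx else ed_secondary_dx
    id_ed <- add_episode("ED", anchor, ed_end, "ED", "HOME", ed_dx, "ED")
    discharge <- ed_end
    death_post <- r_two_piece(1, two_piece_hazard(block$p_death_30d,
                                                  block$p_death_1y))
    if (is.finite(death_post)) {
      death_post <- max(1, ceiling(death_post))
      death_date <- discharge + death_post
    } else death_post <- Inf
    hosp <- recurrent_stays(
      two_piece_hazard(block$p_hosp_30d, block$p_hosp_1y),
      death_post, block$los)
    for (r in seq_len(nrow(hosp))) {
      died_here <- is.finite(death_post) &&
        death_post <= hosp$end[r] && death_post > hosp$start[r]
      add_episode("HOSPITALIZATION", discharge + hosp$start[r],
                  discharge + if (died_here) death_post else hosp$end[r],
                  "internal medicine", if (died_here) "DIED" else "HOME",
                  nonhf_hosp_dx, "INDEX_HOSP")
    }
    re_ed <- recurrent_points(
      two_piece_hazard(block$p_re_ed_30d, block$p_re_ed_1y), death_post)
    for (t in re_ed)
      add_episode("ED", discharge + t, discharge + t, "ED", "HOME",
                  ed_nonhf_dx, "ED")
  }

  # scheduled activity: drawn over the follow-up year, kept while alive
  n_out <- r_count_nb(1, block$outpatient_mean, block$outpatient_sd)
  if (n_out > 0) {
    days <- sort(sample.int(365L, min(n_out, 365L)))
    days <- days[days < death_post]
    for (t in days)
      add_episode("OUTPATIENT", discharge + t, discharge + t,
                  "outpatient clinic", "HOME", "", NULL)
  }
  n_dh <- stats::rpois(1, block$day_hospital_mean)
  if (n_dh > 0) {
    days <- sort(sample.int(365L, min(n_dh, 365L)))
    days <- days[days < death_post]
    for (t in days)
      add_episode("DAY_HOSPITAL", discharge + t, discharge + t,
                  "day hospital", "HOME", "", "DAY_HOSPITAL")
  }

  finish(id_ed, index_hosp_id, death_date,
         if (arm == "hospitalized") "HOSPITALIZED"
         else "DISCHARGED_HOME_FROM_ED")
}

# non-overlapping hospital stays after day 0: first start from the two-piece
# first-event law, later starts after the previous discharge with the late
# hazard; all stays must begin before death and before day 365
recurrent_stays <- function(hz, death_post, los_params) {
  start <- numeric(); end <- numeric()
  t <- r_two_piece(1, hz)
  while (is.finite(t) && t < min(death_post, 365)) {
    t <- max(1, ceiling(t))
    if (t >= min(death_post, 365)) break
    los <- r_los(1, los_params)
    start <- c(start, t); end <- c(end, t + los)
    gap <- stats::rexp(1, max(hz$h2, 1e-12))
    t <- t + los + max(1, ceiling(gap))
    if (hz$h2 <= 0) break
  }
  data.frame(start = start, end = end)
}

# revisit days (point events) after day 0, stopped at death/horizon
recurrent_points <- function(hz, death_post) {
  out <- numeric()
  t <- r_two_piece(1, hz)
  while (is.finite(t) && t < min(death_post, 365)) {
    t <- max(1, ceiling(t))
    if (t >= min(death_post, 365)) break
    out <- c(out, t)
    gap <- stats::rexp(1, max(hz$h2, 1e-12))
    t <- t + max(1, ceiling(gap))
    if (hz$h2 <= 0) break
  }
  out
}

#' Write a synthetic cohort to CSV files
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `episodes.csv`, `vitals.csv`,
#'   `costs.csv`, `truth.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_episodes(cohort$episodes, file.path(dir, "episodes.csv"))
  write_vitals(cohort$vitals, file.path(dir, "vitals.csv"))
  write_costs(cohort$costs, file.path(dir, "costs.csv"))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Recover empirical parameters from generated tables
#'
#' Runs the cohort-construction and outcome machinery on a generated cohort
#' and reports, per HF group of the hospitalized arm, the empirical
#' quantities matching the generator's planted inputs: in-hospital
#' mortality, crude 30-day and 1-year mortality, median index length of
#' stay, 30-day and 1-year readmission and ED-revisit rates, mean outpatient
#' visits and mean episode costs by kind. Used by the tests to assert
#' recovery within sampling error.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @return Data frame, one row per HF group.
#' @export
recover_params <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  strata <- build_strata(cohort$episodes, cohort$vitals,
                         format(min(as.Date(cohort$episodes$start_date)),
                                "%Y"))
  ec <- episode_cost_table(cohort$costs)
  rows <- list()
  for (g in sort(unique(strata$hf_group))) {
    s <- strata[strata$hf_group == g & strata$arm == "HOSPITALIZED", ,
                drop = FALSE]
    if (nrow(s) == 0L) next
    hosp <- cohort$episodes[match(s$index_hosp_id,
                                  cohort$episodes$episode_id), ]
    los <- length_of_stay("HOSPITALIZATION", hosp$start_date, hosp$end_date)
    rate <- function(ev, co)
      event_rate(s, cohort$episodes, cohort$vitals, ev, co)$rate
    idx_cost <- ec$total[match(s$index_hosp_id, ec$episode_id)]
    out_tab <- table(cohort$episodes$patient_id[
      cohort$episodes$kind == "OUTPATIENT"])
    n_out <- as.integer(out_tab[s$patient_id])
    n_out[is.na(n_out)] <- 0L
    rows[[g]] <- data.frame(
      hf_group = g, n = nrow(s),
      p_inhosp_death = mean(hosp$disposition == "DIED"),
      p_death_30d = rate("DEATH", 30L),
      p_death_1y = rate("DEATH", 365L),
      median_los = stats::median(los),
      p_readm_30d = rate("READMISSION", 30L),
      p_readm_1y = rate("READMISSION", 365L),
      p_re_ed_30d = rate("RE_ED_VISIT", 30L),
      p_re_ed_1y = rate("RE_ED_VISIT", 365L),
      outpatient_mean = mean(n_out),
      mean_index_hosp_cost = mean(idx_cost, na.rm = TRUE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
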