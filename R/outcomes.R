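#' @title Clinical outcome statistics
#' @description
#' Crude cumulative event rates (mortality, readmission, ED revisit, first
#' hospitalization) at fixed cut-offs after the index discharge, Kaplan-Meier
#' survival curves, the two-group log-rank test and the usual univariable
#' group comparisons. Rates are crude by design: a patient who dies remains
#' in the denominator and competing risks are not adjusted for, matching how
#' n (%) event rates are conventionally reported from administrative data.
#' @name outcomes_stats
NULL

event_types <- c("DEATH", "READMISSION", "RE_ED_VISIT", "FIRST_HOSPITALIZATION")

#' Crude event rate at a cut-off after index discharge
#'
#' The clock starts at each patient's index discharge date (hospital
#' discharge for hospitalized patients, ED discharge otherwise). A patient
#' counts in the numerator if they have at least one qualifying event in the
#' window `(discharge, discharge + cutoff]`:
#'
#' * `DEATH` — death on or before `discharge + cutoff` (in-hospital deaths,
#'   whose death date does not exceed the discharge date, are included, so
#'   the 30-day rate is cumulative mortality);
#' * `READMISSION` — any non-index hospitalization starting in the window;
#' * `RE_ED_VISIT` — any ED visit after the index ED visit starting in the
#'   window;
#' * `FIRST_HOSPITALIZATION` — any hospitalization in the window (for
#'   patients discharged home from the ED).
#'
#' Patients who died in the ED have no follow-up and are dropped from the
#' denominator.
#'
#' @param strata `"cohort_strata"` rows to evaluate (filter by arm/group
#'   first to reproduce per-stratum rates).
#' @param episodes,vitals Record tables.
#' @param event One of `"DEATH"`, `"READMISSION"`, `"RE_ED_VISIT"`,
#'   `"FIRST_HOSPITALIZATION"`.
#' @param cutoff_days Window length, 30 or 365.
#' @return One-row data frame: `event`, `cutoff_days`, `numerator`,
#'   `denominator`, `rate`.
#' @export
event_rate <- function(strata, episodes, vitals, event,
                       cutoff_days = c(30L, 365L)) {
  event <- match.arg(event, event_types)
  cutoff_days <- cutoff_days[1]
  stopifnot(cutoff_days > 0)
  s <- strata[strata$arm != "DIED_IN_ED", , drop = FALSE]
  if (nrow(s) == 0L) stop("empty cohort")
  if (event == "DEATH") {
    dd <- vitals$death_date[match(s$patient_id, vitals$patient_id)]
    hit <- !is.na(dd) & dd <= s$index_discharge_date + cutoff_days
  } else {
    kind_needed <- if (event == "RE_ED_VISIT") "ED" else "HOSPITALIZATION"
    ep <- episodes[episodes$kind == kind_needed &
                     episodes$patient_id %in% s$patient_id, , drop = FALSE]
    ep$start_date <- as.Date(ep$start_date)
    i <- match(ep$patient_id, s$patient_id)
    d0 <- s$index_discharge_date[i]
    not_index <- if (event == "RE_ED_VISIT")
      ep$episode_id != s$index_episode_id[i]
    else is.na(s$index_hosp_id[i]) | ep$episode_id != s$index_hosp_id[i]
    qualifying <- not_index & ep$start_date > d0 &
      ep$start_date <= d0 + cutoff_days
    hit <- s$patient_id %in% ep$patient_id[qualifying]
  }
  data.frame(event = event, cutoff_days = cutoff_days,
             numerator = sum(hit), denominator = nrow(s),
             rate = sum(hit) / nrow(s))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of survival from the index discharge. Thin layer
#' over [survival::survfit()] returning the step function on the event-day
#' grid.
#'
#' @param time Follow-up days (event or censoring).
#' @param status 1 = death observed, 0 = censored.
#' @return Object of class `"survival_curve"`: data frame `times`,
#'   `survival`, `at_risk`, with the `survfit` fit in attribute `fit`.
#' @export
km_estimate <- function(time, status) {
  stopifnot(length(time) == length(status), all(time >= 0))
  fit <- survival::survfit(survival::Surv(time, status) ~ 1)
  out <- data.frame(times = fit$time, survival = fit$surv,
                    at_risk = fit$n.risk)
  attr(out, "fit") <- fit
  class(out) <- c("survival_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' @param time_a,status_a Follow-up days and death indicators, group A.
#' @param time_b,status_b Same for group B.
#' @return One-row data frame: `test_name = "log_rank"`, `statistic`
#'   (chi-square, 1 df), `p_value`.
#' @export
log_rank <- function(time_a, status_a, time_b, status_b) {
  if (sum(status_a) + sum(status_b) == 0)
    stop("log-rank test undefined: no events in either group")
  time <- c(time_a, time_b)
  status <- c(status_a, status_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, status) ~ grp)
  data.frame(test_name = "log_rank", statistic = sd$chisq,
             p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariable two-group comparison
#'
#' Dispatches on the measurement scale the analyst declares: Student's
#' t-test for normally distributed continuous variables, the Mann-Whitney U
#' test for skewed ones, and the chi-square test (without continuity
#' correction) for categorical counts. Normality is a caller decision, not
#' auto-tested.
#'
#' @param a,b For continuous scales, the two samples; for `"categorical"`,
#'   the two rows of the contingency table (counts per category).
#' @param scale `"continuous_normal"`, `"continuous_skewed"` or
#'   `"categorical"`.
#' @return One-row data frame: `test_name`, `statistic`, `p_value`.
#' @export
#' @examples
#' compare_groups(c(10, 90), c(20, 80), "categorical")  # chi-square 3.92
compare_groups <- function(a, b, scale = c("continuous_normal",
                                           "continuous_skewed",
                                           "categorical")) {
  scale <- match.arg(scale)
  if (length(a) == 0L || length(b) == 0L) stop("empty group")
  switch(scale,
    continuous_normal = {
      t <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(test_name = "t", statistic = unname(t$statistic),
                 p_value = t$p.value)
    },
    continuous_skewed = {
      w <- stats::wilcox.test(a, b, exact = FALSE)
      data.frame(test_name = "mann_whitney",
                 statistic = unname(w$statistic), p_value = w$p.value)
    },
    categorical = {
      stopifnot(length(a) == length(b))
      tab <- rbind(a, b)
      if (identical(a, b)) {
        # degenerate but well-defined: identical distributions carry no
        # evidence against homogeneity
        return(data.frame(test_name = "chi_square", statistic = 0,
                          p_value = 1))
      }
      ch <- stats::chisq.test(tab, correct = FALSE)
      data.frame(test_name = "chi_square", statistic = unname(ch$statistic),
                 p_value = ch$p.value)
    })
}

#' Event rates for every group/arm/event/cut-off combination
#'
#' Convenience roll-up used by the command-line interface and the report:
#' loops [event_rate()] over HF group, disposition arm, event type and
#' cut-off, picking the event types that make sense for each arm
#' (readmission for hospitalized patients, first hospitalization for
#' patients discharged home).
#'
#' @param strata,episodes,vitals As in [event_rate()].
#' @param cutoffs Cut-offs in days.
#' @return Data frame with one row per combination plus `arm` and
#'   `hf_group` columns.
#' @export
outcome_table <- function(strata, episodes, vitals, cutoffs = c(30L, 365L)) {
  rows <- list()
  for (arm in intersect(c("HOSPITALIZED", "DISCHARGED_HOME_FROM_ED"),
                        unique(strata$arm))) {
    events <- if (arm == "HOSPITALIZED")
      c("DEATH", "READMISSION", "RE_ED_VISIT")
    else c("DEATH", "FIRST_HOSPITALIZATION", "RE_ED_VISIT")
    for (grp in sort(unique(strata$hf_group))) {
      s <- strata[strata$arm == arm & strata$hf_group == grp, , drop = FALSE]
      if (nrow(s) == 0L) next
      for (ev in events) for (co in cutoffs) {
        r <- event_rate(s, episodes, vitals, ev, co)
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(arm = arm, hf_group = grp), r)
      }
    }
  }
  do.call(rbind, rows)
}
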