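#' Published reference aggregates for a hospitalized heart-failure cohort
#'
#' Aggregate utilization and cost figures reported for a real-world cohort
#' of adult heart-failure patients hospitalized after an ED visit during
#' calendar year 2018 at a single tertiary centre, split by primary (pHF,
#' n = 1,029) versus secondary (sHF, n = 1,257) HF diagnosis. The
#' patient-level data behind these aggregates are access-restricted; the
#' package therefore uses the printed totals both as the validation target
#' for its derived-cost arithmetic (see [reference_cost_checks()]) and as
#' calibration defaults for the synthetic cohort generator.
#'
#' All costs are euros over a fixed 365-day journey per patient.
#'
#' @return Data frame with one row per HF group: cohort size, episode
#'   counts and total costs by clinical status, and per-episode mean costs.
#' @export
#' @examples
#' reference_cost_aggregates()
reference_cost_aggregates <- function() {
  data.frame(
    hf_group = c("pHF", "sHF"),
    n_patients = c(1029L, 1257L),
    total_cost = c(9144952, 12262422),
    ed_cost = c(882295.1, 1035105.6),
    hospital_cost = c(8030614.7, 10628470.6),
    index_hosp_cost = c(4020987.5, 5852662.5),
    readmission_cost = c(4009627.2, 4775808.1),
    day_hospital_cost = c(232041.8, 598846.2),
    n_episodes = c(4925L, 6098L),
    n_ed_episodes = c(2571L, 3013L),
    n_day_hospital_episodes = c(427L, 812L),
    n_hospital_episodes = c(1927L, 2273L),
    n_index_hosp_episodes = c(1029L, 1257L),
    n_readmission_episodes = c(898L, 1016L),
    mean_ed_episode_cost = c(343.2, 343.5),
    mean_day_hospital_episode_cost = c(543.4, 737.5),
    mean_index_hosp_episode_cost = c(3907.7, 4656.1),
    mean_readmission_episode_cost = c(4465.1, 4700.6)
  )
}

#' Derived quantities from the reference aggregates
#'
#' Recomputes, from the printed reference inputs only, every derived figure
#' of the cost table and the relative pHF-vs-sHF differences: total
#' patient-days (n x 365), mean cost per patient journey, per patient-day
#' and per episode, the sHF index-hospitalization episode mean, and the
#' relative excess of sHF over pHF for total cost, journey mean and the
#' per-episode means (as percentages).
#'
#' @param horizon Journey length in days (365).
#' @return Named list of numeric values; percentages are on the 0-100
#'   scale.
#' @export
reference_cost_checks <- function(horizon = 365L) {
  ref <- reference_cost_aggregates()
  p <- ref[ref$hf_group == "pHF", ]
  s <- ref[ref$hf_group == "sHF", ]
  list(
    patient_days_pHF = p$n_patients * horizon,
    patient_days_sHF = s$n_patients * horizon,
    mean_cost_per_journey_pHF = p$total_cost / p$n_patients,
    mean_cost_per_journey_sHF = s$total_cost / s$n_patients,
    mean_cost_per_patient_day_pHF = p$total_cost / (p$n_patients * horizon),
    mean_cost_per_patient_day_sHF = s$total_cost / (s$n_patients * horizon),
    mean_cost_per_episode_pHF = p$total_cost / p$n_episodes,
    mean_cost_per_episode_sHF = s$total_cost / s$n_episodes,
    mean_index_hosp_episode_cost_sHF =
      s$index_hosp_cost / s$n_index_hosp_episodes,
    mean_index_hosp_episode_cost_pHF =
      p$index_hosp_cost / p$n_index_hosp_episodes,
    pct_total_cost_excess_sHF = 100 * pct_diff(s$total_cost, p$total_cost),
    pct_journey_mean_excess_sHF = 100 * pct_diff(
      s$total_cost / s$n_patients, p$total_cost / p$n_patients),
    pct_index_hosp_episode_excess_sHF = 100 * pct_diff(
      s$mean_index_hosp_episode_cost, p$mean_index_hosp_episode_cost),
    pct_readmission_episode_excess_sHF = 100 * pct_diff(
      s$mean_readmission_episode_cost, p$mean_readmission_episode_cost),
    pct_day_hospital_episode_excess_sHF = 100 * pct_diff(
      s$mean_day_hospital_episode_cost, p$mean_day_hospital_episode_cost)
  )
}
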