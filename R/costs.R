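#' @title Episode and patient-journey costing
#' @description
#' Full-costing arithmetic: each episode's cost is the sum of directly
#' imputable costs, priced catalog activity, and a residual share of costs
#' that cannot be attributed to any single episode, allocated here per diem
#' (proportional to occupied days). All monetary arithmetic is carried out
#' at cent precision with largest-remainder reconciliation, so every
#' conservation identity (items to episodes to journeys to group totals)
#' holds exactly.
#' @name cost_model
NULL

#' Roll up one episode's cost items
#'
#' @param items Cost-item rows sharing a single `episode_id`.
#' @return One-row data frame: `episode_id`, `direct`, `catalog`,
#'   `residual`, `total` (euros). An empty item list yields all zeros.
#' @export
episode_cost <- function(items) {
  if (nrow(items) == 0L)
    return(data.frame(episode_id = NA_character_, direct = 0, catalog = 0,
                      residual = 0, total = 0))
  if (length(unique(items$episode_id)) != 1L)
    stop("episode_cost() expects items of a single episode")
  if (any(is.na(items$amount) | items$amount < 0))
    stop("negative or missing cost amount")
  by_cat <- function(cat) sum(items$amount[items$category == cat])
  d <- by_cat("DIRECT"); c_ <- by_cat("CATALOG"); r <- by_cat("RESIDUAL")
  data.frame(episode_id = items$episode_id[1], direct = d, catalog = c_,
             residual = r, total = d + c_ + r)
}

#' Roll up a whole cost ledger to per-episode totals
#'
#' @param costs Cost-item table ([read_costs()] layout).
#' @return Data frame with one row per episode id: `episode_id`, `direct`,
#'   `catalog`, `residual`, `total`.
#' @export
episode_cost_table <- function(costs) {
  if (any(is.na(costs$amount) | costs$amount < 0))
    stop("negative or missing cost amount")
  sum_cat <- function(cat) {
    x <- costs[costs$category == cat, ]
    out <- tapply(x$amount, x$episode_id, sum)
    out
  }
  ids <- sort(unique(costs$episode_id))
  pick <- function(tab) ifelse(ids %in% names(tab), tab[ids], 0)
  d <- pick(sum_cat("DIRECT"))
  ct <- pick(sum_cat("CATALOG"))
  r <- pick(sum_cat("RESIDUAL"))
  data.frame(episode_id = ids, direct = unname(d), catalog = unname(ct),
             residual = unname(r), total = unname(d + ct + r),
             row.names = NULL)
}

#' Allocate a residual cost pool across episodes per diem
#'
#' Costs that cannot be imputed directly to any episode are transferred
#' proportionally to each episode's occupied days (hospitalizations:
#' discharge minus admission, minimum 1; other kinds: calendar dates
#' touched). Shares are rounded to whole cents by the largest-remainder
#' rule so they sum to the pool exactly.
#'
#' @param pool Residual pool in euros (non-negative).
#' @param episodes Episode rows receiving the allocation.
#' @param weight Allocation weight; only `"LOS_DAYS"` (per diem) is defined.
#' @return Cost-item data frame (`category = "RESIDUAL"`), one row per
#'   episode, amounts summing to `round(pool, 2)`.
#' @export
#' @examples
#' eps <- data.frame(episode_id = c("h1", "h2"), kind = "HOSPITALIZATION",
#'                   start_date = as.Date(c("2018-01-01", "2018-02-01")),
#'                   end_date = as.Date(c("2018-01-04", "2018-02-08")))
#' allocate_residual(1000, eps)  # 300 and 700
allocate_residual <- function(pool, episodes, weight = "LOS_DAYS") {
  stopifnot(pool >= 0, weight == "LOS_DAYS", nrow(episodes) >= 1L)
  days <- as.numeric(as.Date(episodes$end_date) -
                       as.Date(episodes$start_date))
  w <- ifelse(episodes$kind == "HOSPITALIZATION", pmax(days, 1), days + 1)
  amounts <- split_amount(pool, w)
  data.frame(episode_id = episodes$episode_id, category = "RESIDUAL",
             description = "per-diem residual allocation",
             quantity = NA_real_, unit_cost = NA_real_, amount = amounts)
}

#' Costs of a cohort's patient journeys, by group
#'
#' Aggregates episode costs over each HF group's journeys under the fixed
#' follow-up horizon: group totals, mean cost per patient journey, mean cost
#' per patient-day, splits by clinical status (ED, index hospitalization,
#' readmissions, day hospital) with percentages of total, and per-episode
#' kind counts and mean costs. Only episodes starting within
#' `[index admission, index admission + horizon)` are counted.
#'
#' @param strata `"cohort_strata"` rows (typically one arm).
#' @param episodes Episode table.
#' @param episode_costs Per-episode totals from [episode_cost_table()].
#' @param horizon Journey length in days (default 365).
#' @return Object of class `"journey_cost_summary"`: list with elements
#'   `by_group` (one row per group: n, patient_days, totals and means),
#'   `by_status` (status splits and percentages) and `by_kind` (episode
#'   counts and mean costs per kind).
#' @export
journey_cost_summary <- function(strata, episodes, episode_costs,
                                 horizon = 365L) {
  s <- strata[strata$arm != "DIED_IN_ED", , drop = FALSE]
  if (nrow(s) == 0L) stop("no patients to summarise")
  episodes$start_date <- as.Date(episodes$start_date)
  groups <- sort(unique(s$hf_group))
  bg <- list(); bs <- list(); bk <- list()
  for (g in groups) {
    sg <- s[s$hf_group == g, , drop = FALSE]
    n <- nrow(sg)
    anchors <- stats::setNames(sg$index_admission_date, sg$patient_id)
    ep <- episodes[episodes$patient_id %in% sg$patient_id, , drop = FALSE]
    a <- anchors[ep$patient_id]
    ep <- ep[ep$start_date >= a & ep$start_date < a + horizon, , drop = FALSE]
    ep$cost <- episode_costs$total[match(ep$episode_id,
                                         episode_costs$episode_id)]
    costed <- ep[ep$kind %in% c("ED", "HOSPITALIZATION", "DAY_HOSPITAL"), ,
                 drop = FALSE]
    if (any(is.na(costed$cost)))
      stop("episodes without a cost in group ", g, ": ",
           paste(utils::head(costed$episode_id[is.na(costed$cost)], 5),
                 collapse = ", "))
    is_index_hosp <- costed$episode_id %in% sg$index_hosp_id
    status <- ifelse(costed$kind == "ED", "ED",
                     ifelse(costed$kind == "DAY_HOSPITAL", "DAY_HOSPITAL",
                            ifelse(is_index_hosp, "INDEX_HOSPITALIZATION",
                                   "READMISSION")))
    total <- sum(costed$cost)
    st <- tapply(costed$cost, factor(status,
                                     c("ED", "INDEX_HOSPITALIZATION",
                                       "READMISSION", "DAY_HOSPITAL")),
                 sum, default = 0)
    # mean days at ED / in hospital among users of each service
    ep_by_pt <- split(ep, ep$patient_id)
    no_vitals <- data.frame(patient_id = character(),
                            death_date = as.Date(character()))
    js <- lapply(seq_len(nrow(sg)), function(i) {
      summarize_journey(patient_journey(
        sg$patient_id[i], ep_by_pt[[sg$patient_id[i]]] %||% ep[0, ],
        no_vitals, sg$index_admission_date[i], horizon,
        stats::na.omit(c(sg$index_episode_id[i], sg$index_hosp_id[i]))))
    })
    js <- do.call(rbind, js)
    mean_pos <- function(x) if (any(x > 0)) mean(x[x > 0]) else NA_real_
    bg[[g]] <- data.frame(
      hf_group = g, n_patients = n, patient_days = n * horizon,
      total_cost = total,
      mean_cost_per_journey = total / n,
      mean_cost_per_patient_day = total / (n * horizon),
      n_episodes = nrow(costed),
      mean_cost_per_episode = total / nrow(costed),
      mean_days_ed = mean_pos(js$days_with_ED_visit),
      mean_days_hospital = mean_pos(js$days_in_hospital))
    bs[[g]] <- data.frame(
      hf_group = g, status = names(st), cost = as.numeric(st),
      pct_of_total = 100 * as.numeric(st) / total)
    kind_stats <- lapply(split(costed, status), function(x)
      data.frame(n_episodes = nrow(x), mean_cost = mean(x$cost),
                 sd_cost = stats::sd(x$cost), cost = sum(x$cost)))
    bk[[g]] <- cbind(hf_group = g, status = names(kind_stats),
                     do.call(rbind, kind_stats))
  }
  out <- list(by_group = do.call(rbind, bg),
              by_status = do.call(rbind, bs),
              by_kind = do.call(rbind, bk),
              horizon = horizon)
  rownames(out$by_group) <- rownames(out$by_status) <-
    rownames(out$by_kind) <- NULL
  class(out) <- "journey_cost_summary"
  out
}

#' @export
print.journey_cost_summary <- function(x, ...) {
  cat("Journey costs over a", x$horizon, "day horizon\n")
  print(x$by_group, row.names = FALSE)
  cat("\nBy clinical status:\n")
  print(x$by_status, row.names = FALSE)
  invisible(x)
}

#' Daily and cumulative cost curve of one journey
#'
#' Each episode's total cost is spread uniformly over the days it occupies
#' within the horizon (point episodes charge their single day); the
#' cumulative curve is the running sum, ending at the journey total.
#'
#' @param journey A `"patient_journey"`.
#' @param episode_costs Per-episode totals from [episode_cost_table()].
#' @return Data frame `day` (0-based), `cost`, `cumulative`.
#' @export
daily_cost_curve <- function(journey, episode_costs) {
  h <- journey$horizon
  daily <- numeric(h)
  ep <- journey$episodes
  for (i in seq_len(nrow(ep))) {
    total <- episode_costs$total[match(ep$episode_id[i],
                                       episode_costs$episode_id)]
    if (is.na(total)) next
    d <- episode_days(ep$kind[i], ep$start_date[i], ep$end_date[i],
                      journey$anchor)
    d <- d[d >= 0 & d < h]
    if (length(d) == 0L) next
    daily[d + 1] <- daily[d + 1] + split_amount(total, rep(1, length(d)))
  }
  data.frame(day = seq_len(h) - 1L, cost = daily, cumulative = cumsum(daily))
}
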