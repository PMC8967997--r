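#' @title Composite-outcome charts and the summary report
#' @description
#' The stacked-area composite-outcome chart plots, for each follow-up day,
#' the percentage of the cohort in each clinical state, stacked in priority
#' order (death at the base of the stack, time at home on top). The numeric
#' stacking layer is exposed separately from the rendered image so it can be
#' tested without pixel comparisons.
#' @name viz_report
NULL

#' Default plot specification
#'
#' One colour per clinical state (mortality black, index ED visit light
#' green, index hospitalization brown, home light blue, outpatient light
#' yellow, ED revisits dark green, readmissions light brown).
#'
#' @param title Plot title.
#' @return List with elements `colors` (named, one per state) and `title`.
#' @export
coherent_plot_spec <- function(title = "Composite outcome") {
  list(colors = c(
    DEAD = "black",
    IN_HOSPITAL_INDEX = "#8B5A2B",
    IN_HOSPITAL_READMISSION = "#D2B48C",
    IN_ED_INDEX = "#90EE90",
    IN_ED_REVISIT = "#006400",
    DAY_HOSPITAL = "#FFA500",
    OUTPATIENT_VISIT = "#FFFACD",
    AT_HOME = "#ADD8E6"),
    title = title)
}

#' Stacking layer of the composite-outcome chart
#'
#' Long-format cumulative bounds for each (day, state) cell: states are
#' stacked in priority order with `DEAD` at the base, so `ymax` of the last
#' state is 1 on every day.
#'
#' @param matrix A `"daily_state_matrix"` from [occupancy()].
#' @return Data frame `day`, `state`, `fraction`, `ymin`, `ymax`.
#' @export
stack_occupancy <- function(matrix) {
  states <- clinical_states()
  stopifnot(all(colnames(matrix) == states))
  sums <- rowSums(matrix)
  if (any(abs(sums - 1) > 1e-9))
    stop("occupancy columns must sum to 1; worst deviation ",
         max(abs(sums - 1)))
  h <- nrow(matrix)
  long <- data.frame(
    day = rep(seq_len(h) - 1L, times = length(states)),
    state = factor(rep(states, each = h), levels = states),
    fraction = as.vector(matrix[, states]))
  cum <- t(apply(matrix[, states, drop = FALSE], 1, cumsum))
  long$ymax <- as.vector(cum)
  long$ymin <- long$ymax - long$fraction
  long
}

#' Stacked-area composite-outcome chart
#'
#' @param matrix A `"daily_state_matrix"`.
#' @param spec Plot specification from [coherent_plot_spec()].
#' @param file Optional output path (`.png` or `.svg`); when given the
#'   image is written there.
#' @param width,height Device size in inches.
#' @return List of class `"coherent_plot"`: `plot` (a ggplot) and `data`
#'   (the stacking layer from [stack_occupancy()]).
#' @export
coherent_plot <- function(matrix, spec = coherent_plot_spec(), file = NULL,
                          width = 7, height = 4.5) {
  long <- stack_occupancy(matrix)
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$day, ymin = .data$ymin * 100, ymax = .data$ymax * 100,
    fill = .data$state)) +
    ggplot2::geom_ribbon() +
    ggplot2::scale_fill_manual(values = spec$colors, name = NULL) +
    ggplot2::labs(title = spec$title, x = "Day of follow-up",
                  y = "% of patients") +
    ggplot2::scale_y_continuous(limits = c(0, 100), expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = width,
                                      height = height, dpi = 150)
  structure(list(plot = p, data = long), class = "coherent_plot")
}

#' Mean time-in-state fractions per group
#'
#' The numeric layer of the horizontal proportion bars: for each group, the
#' mean over patients of the fraction of the horizon spent in each state
#' category. Fractions sum to 1 per group.
#'
#' @param summaries Named list: one data frame of [summarize_journey()] rows
#'   per group.
#' @return Data frame `group`, `state`, `fraction`.
#' @export
proportion_data <- function(summaries) {
  stopifnot(length(summaries) >= 1L)
  cats <- c(days_dead = "DEAD", days_in_hospital = "IN_HOSPITAL",
            days_with_ED_visit = "IN_ED", days_in_day_hospital = "DAY_HOSPITAL",
            days_with_outpatient_visit = "OUTPATIENT_VISIT",
            days_at_home = "AT_HOME")
  rows <- lapply(names(summaries), function(g) {
    s <- summaries[[g]]
    horizon <- rowSums(s[names(cats)])
    data.frame(group = g, state = unname(cats),
               fraction = colMeans(s[names(cats)] / horizon))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Horizontal 100%-stacked bars of time spent per clinical condition
#'
#' @param summaries As in [proportion_data()].
#' @param file Optional output image path.
#' @param width,height Device size in inches.
#' @return List of class `"coherent_plot"`: `plot` and `data`
#'   (from [proportion_data()]).
#' @export
proportion_bars <- function(summaries, file = NULL, width = 7, height = 2.5) {
  pd <- proportion_data(summaries)
  pal <- c(DEAD = "black", IN_HOSPITAL = "#8B5A2B", IN_ED = "#006400",
           DAY_HOSPITAL = "#FFA500", OUTPATIENT_VISIT = "#FFFACD",
           AT_HOME = "#ADD8E6")
  pd$state <- factor(pd$state, levels = names(pal))
  p <- ggplot2::ggplot(pd, ggplot2::aes(
    x = .data$fraction * 100, y = .data$group, fill = .data$state)) +
    ggplot2::geom_col(position = ggplot2::position_stack(reverse = TRUE)) +
    ggplot2::scale_fill_manual(values = pal, name = NULL) +
    ggplot2::labs(x = "% of follow-up time", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = width,
                                      height = height, dpi = 150)
  structure(list(plot = p, data = pd), class = "coherent_plot")
}

#' Assemble a markdown summary report
#'
#' Gathers the stage outputs of a full pipeline run — strata counts, event
#' rates, journey cost summaries and pre-rendered figures — into one
#' markdown document mirroring the usual results layout (rates first, then
#' the cost table, then the composite-outcome figures).
#'
#' @param strata `"cohort_strata"`.
#' @param event_rates Output of [outcome_table()].
#' @param cost_summary `"journey_cost_summary"`.
#' @param figures Named character vector/list of image paths to embed
#'   (optional).
#' @param file Output markdown path.
#' @return `file`, invisibly.
#' @export
coherent_report <- function(strata, event_rates, cost_summary,
                            figures = list(), file) {
  for (nm in c("strata", "event_rates", "cost_summary")) {
    if (is.null(get(nm))) stop("missing stage output: ", nm)
  }
  md_table <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) round(x, 3))
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste("|", paste(unlist(df[i, ]), collapse = " | "), "|"), ""))
  }
  lines <- c(
    "# Cohort composite-outcome report", "",
    "## Cohort strata", "",
    md_table(as.data.frame(table(arm = strata$arm,
                                 hf_group = strata$hf_group))), "",
    "## Event rates", "",
    md_table(event_rates), "",
    "## Journey costs", "",
    md_table(cost_summary$by_group), "",
    md_table(cost_summary$by_status), "")
  if (length(figures)) {
    lines <- c(lines, "## Figures", "",
               unlist(lapply(names(figures), function(nm)
                 c(sprintf("![%s](%s)", nm, figures[[nm]]), ""))))
  }
  writeLines(lines, file)
  invisible(file)
}
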