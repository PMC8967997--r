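#' @title Episode, vital-status and cost tables: schemas and I/O
#' @description
#' The package exchanges three flat CSV tables, one row per record:
#'
#' * `episodes.csv` — patient_id, episode_id, kind, start_date, end_date,
#'   department, disposition, diagnoses
#' * `vitals.csv` — patient_id, death_date (empty when alive)
#' * `costs.csv` — episode_id, category, description, quantity, unit_cost,
#'   amount
#'
#' Dates are ISO-8601 (`YYYY-MM-DD`); both interval endpoints are calendar
#' dates and intervals are closed at the file level (half-open hospital-day
#' conventions are applied downstream, not in the format). Diagnoses are
#' packed into one `|`-separated column of `system:code:position:poa`
#' fragments, e.g. `"ICD10CM:I50.9:2:Y"`; an empty position field encodes a
#' code whose rank could not be established. Encoding is UTF-8, the delimiter
#' a comma and the decimal mark a point; none of these are configurable so
#' round-trips are bit-exact. A machine-readable copy of the schemas ships in
#' `system.file("extdata", "schemas.json", package = "coherentHF")`.
#' @name records_io
NULL

episode_columns <- c("patient_id", "episode_id", "kind", "start_date",
                     "end_date", "department", "disposition", "diagnoses")
vital_columns <- c("patient_id", "death_date")
cost_columns <- c("episode_id", "category", "description", "quantity",
                  "unit_cost", "amount")

#' Parse a packed diagnosis field
#'
#' @param packed Character scalar, `|`-separated `system:code:position:poa`
#'   fragments; `""` means no coded diagnosis.
#' @return Data frame with columns `system`, `code`, `position` (integer,
#'   `NA` when the rank is undefined) and `poa` (logical, `NA` when not
#'   flagged).
#' @export
#' @examples
#' parse_diagnoses("ICD10CM:J18.9:1:Y|ICD10CM:I50.9:2:Y")
parse_diagnoses <- function(packed) {
  stopifnot(is.character(packed), length(packed) == 1L)
  if (is.na(packed) || !nzchar(packed)) {
    return(data.frame(system = character(), code = character(),
                      position = integer(), poa = logical()))
  }
  parts <- strsplit(strsplit(packed, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
  nlen <- vapply(parts, length, 1L)
  if (any(nlen < 2L | nlen > 4L))
    stop("malformed diagnosis fragment: ", packed)
  # strsplit drops trailing empty fields (absent position / POA flag)
  parts <- lapply(parts, function(x) {
    length(x) <- 4L
    x[is.na(x)] <- ""
    x
  })
  out <- data.frame(
    system = vapply(parts, `[`, "", 1L),
    code = vapply(parts, `[`, "", 2L),
    position = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
    poa = c("Y" = TRUE, "N" = FALSE)[vapply(parts, `[`, "", 4L)],
    row.names = NULL
  )
  if (any(!out$system %in% c("ICD10CM", "ICPC2")))
    stop("unknown coding system in: ", packed)
  if (any(!nzchar(out$code))) stop("empty diagnosis code in: ", packed)
  if (any(!is.na(out$position) & out$position < 1L))
    stop("diagnosis position must be >= 1 in: ", packed)
  pos <- out$position[!is.na(out$position)]
  if (anyDuplicated(pos)) stop("duplicate diagnosis position in: ", packed)
  out
}

#' Pack a diagnosis table back into the delimited field
#' @param diag Data frame as returned by [parse_diagnoses()].
#' @return Character scalar.
#' @export
pack_diagnoses <- function(diag) {
  if (nrow(diag) == 0L) return("")
  paste(diag$system, diag$code,
        ifelse(is.na(diag$position), "", diag$position),
        ifelse(is.na(diag$poa), "", ifelse(diag$poa, "Y", "N")),
        sep = ":", collapse = "|")
}

validate_episodes <- function(df) {
  msgs <- character()
  row_bad <- rep(FALSE, nrow(df))
  flag <- function(i, msg) {
    row_bad[i] <<- TRUE
    msgs <<- c(msgs, sprintf("row %d: %s", i, msg))
  }
  for (i in seq_len(nrow(df))) {
    if (!df$kind[i] %in% episode_kinds())
      flag(i, paste("unknown kind", df$kind[i]))
    if (is.na(df$start_date[i]) || is.na(df$end_date[i])) {
      flag(i, "unparseable date")
      next
    }
    if (df$end_date[i] < df$start_date[i])
      flag(i, "end_date before start_date")
    if (df$kind[i] %in% c("OUTPATIENT", "DAY_HOSPITAL") &&
        df$end_date[i] != df$start_date[i])
      flag(i, paste(df$kind[i], "episode must be a single calendar date"))
    if (!df$disposition[i] %in% dispositions())
      flag(i, paste("unknown disposition", df$disposition[i]))
    diag <- tryCatch(parse_diagnoses(df$diagnoses[i]), error = function(e) e)
    if (inherits(diag, "error")) {
      flag(i, conditionMessage(diag))
    } else if (any(diag$system == "ICPC2") && df$kind[i] != "ED") {
      flag(i, "ICPC2 codes are only valid on ED episodes")
    }
  }
  list(bad = row_bad, messages = msgs)
}

read_table_checked <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8", check.names = FALSE)
  missing <- setdiff(columns, names(df))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  df[columns]
}

finish_read <- function(df, chk, on_invalid, what) {
  if (any(chk$bad)) {
    if (on_invalid == "error")
      stop(what, " contains invalid rows:\n  ",
           paste(chk$messages, collapse = "\n  "))
    message(sum(chk$bad), " invalid ", what, " row(s) rejected")
    df <- df[!chk$bad, , drop = FALSE]
  }
  attr(df, "n_rejected") <- sum(chk$bad)
  rownames(df) <- NULL
  df
}

#' Read an episode table
#'
#' @param path Path to an `episodes.csv` file.
#' @param on_invalid `"error"` (default) aborts on the first batch of invalid
#'   rows, naming each offending line; `"drop"` discards invalid rows and
#'   records their count in the `n_rejected` attribute.
#' @return Data frame of episodes, dates converted to `Date`, sorted by
#'   `(patient_id, start_date)`.
#' @export
read_episodes <- function(path, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  df <- read_table_checked(path, episode_columns)
  df$start_date <- as.Date(df$start_date, format = "%Y-%m-%d")
  df$end_date <- as.Date(df$end_date, format = "%Y-%m-%d")
  chk <- validate_episodes(df)
  df <- finish_read(df, chk, on_invalid, "episode")
  df[order(df$patient_id, df$start_date, df$episode_id), , drop = FALSE] ->
    df
  rownames(df) <- NULL
  df
}

#' Write an episode table
#'
#' Validates every record first (nothing is written if any record is
#' invalid), then writes the documented CSV schema deterministically so that
#' [read_episodes()] inverts it field-for-field.
#'
#' @param episodes Data frame with the episode columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  stopifnot(is.data.frame(episodes))
  missing <- setdiff(episode_columns, names(episodes))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  df <- episodes[episode_columns]
  df$start_date <- as.Date(df$start_date)
  df$end_date <- as.Date(df$end_date)
  chk <- validate_episodes(df)
  if (any(chk$bad))
    stop("refusing to write invalid episodes:\n  ",
         paste(chk$messages, collapse = "\n  "))
  df$start_date <- format(df$start_date, "%Y-%m-%d")
  df$end_date <- format(df$end_date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a vital-status table
#'
#' One row per patient; `death_date` empty for patients alive at the end of
#' registry follow-up.
#'
#' @inheritParams read_episodes
#' @return Data frame with `patient_id` (character) and `death_date`
#'   (`Date`, `NA` when alive).
#' @export
read_vitals <- function(path, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  df <- read_table_checked(path, vital_columns)
  raw <- df$death_date
  df$death_date <- as.Date(raw, format = "%Y-%m-%d")
  bad <- (nzchar(raw) & !is.na(raw) & is.na(df$death_date)) |
    duplicated(df$patient_id) | duplicated(df$patient_id, fromLast = TRUE)
  msgs <- sprintf("row %d: %s", which(bad),
                  ifelse(is.na(df$death_date[bad]) & nzchar(raw[bad]),
                         "unparseable death_date", "duplicate patient_id"))
  df <- finish_read(df, list(bad = bad, messages = msgs), on_invalid, "vital")
  df
}

#' Write a vital-status table
#' @param vitals Data frame with `patient_id` and `death_date`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vitals <- function(vitals, path) {
  stopifnot(is.data.frame(vitals))
  missing <- setdiff(vital_columns, names(vitals))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(vitals$patient_id))
    stop("refusing to write: duplicate patient_id")
  df <- vitals[vital_columns]
  df$death_date <- ifelse(is.na(df$death_date),
                          "", format(as.Date(df$death_date), "%Y-%m-%d"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

validate_costs <- function(df) {
  msgs <- character()
  bad <- rep(FALSE, nrow(df))
  flag <- function(i, msg) {
    bad[i] <<- TRUE
    msgs <<- c(msgs, sprintf("row %d: %s", i, msg))
  }
  for (i in seq_len(nrow(df))) {
    if (!df$category[i] %in% cost_categories())
      flag(i, paste("unknown category", df$category[i]))
    if (is.na(df$amount[i]) || df$amount[i] < 0)
      flag(i, "amount missing or negative")
    if (identical(df$category[i], "CATALOG")) {
      if (is.na(df$quantity[i]) || is.na(df$unit_cost[i])) {
        flag(i, "CATALOG item needs quantity and unit_cost")
      } else if (abs(df$quantity[i] * df$unit_cost[i] - df$amount[i]) > 0.005) {
        flag(i, "CATALOG amount != quantity * unit_cost")
      }
    }
  }
  list(bad = bad, messages = msgs)
}

#' Read a cost-item table
#' @inheritParams read_episodes
#' @return Data frame of cost line items (`quantity`, `unit_cost`, `amount`
#'   numeric; `quantity`/`unit_cost` are `NA` except for CATALOG items).
#' @export
read_costs <- function(path, on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  df <- read_table_checked(path, cost_columns)
  for (col in c("quantity", "unit_cost", "amount"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  finish_read(df, validate_costs(df), on_invalid, "cost")
}

#' Write a cost-item table
#' @param costs Data frame with the cost columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_costs <- function(costs, path) {
  stopifnot(is.data.frame(costs))
  missing <- setdiff(cost_columns, names(costs))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  df <- costs[cost_columns]
  chk <- validate_costs(df)
  if (any(chk$bad))
    stop("refusing to write invalid cost items:\n  ",
         paste(chk$messages, collapse = "\n  "))
  df$quantity <- ifelse(is.na(df$quantity), "",
                        sprintf("%g", df$quantity))
  for (col in c("unit_cost", "amount"))
    df[[col]] <- ifelse(is.na(df[[col]]), "", sprintf("%.2f", df[[col]]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
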