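# EMD log ingestion: actuation events -> per-patient half-day dose grids.
#
# A "dose" is one or more actuations within a 12-hour half-day window
# (midnight to midday, midday to midnight). Days inside declared device
# malfunction periods are masked as unobserved and excluded from all
# denominators downstream.

#' Parse an EMD actuation event log
#'
#' Reads a delimited file (or data frame) with columns `patient_id`,
#' `timestamp` (ISO 8601) and `n_actuations`, validates every row and
#' returns events sorted by patient and time.
#'
#' @param source Path to a CSV file, or a data frame already in memory.
#' @return Data frame of events with `timestamp` as POSIXct (UTC), sorted
#'   by (`patient_id`, `timestamp`).
#' @export
parse_event_log <- function(source) {
  df <- if (is.data.frame(source)) source else {
    utils::read.csv(source, stringsAsFactors = FALSE, colClasses = "character")
  }
  required <- c("patient_id", "timestamp", "n_actuations")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("event log is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!nrow(df)) {
    return(data.frame(patient_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      n_actuations = integer(), stringsAsFactors = FALSE))
  }
  ts <- parse_iso_datetime(df$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop(sprintf("unparseable timestamp on data line(s) %s (e.g. %s)",
                 paste(utils::head(bad, 5), collapse = ", "),
                 deparse(df$timestamp[bad[1]])), call. = FALSE)
  }
  n_act <- suppressWarnings(as.integer(df$n_actuations))
  if (anyNA(n_act) || any(n_act < 1)) {
    bad <- which(is.na(n_act) | n_act < 1)
    stop(sprintf("invalid n_actuations (must be integer >= 1) on data line(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(patient_id = as.character(df$patient_id),
                    timestamp = ts, n_actuations = n_act,
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

parse_iso_datetime <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  formats <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
               "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")
  ts <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                   origin = "1970-01-01")
  for (fmt in formats) {
    todo <- is.na(ts)
    if (!any(todo)) break
    ts[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  ts
}

#' Parse a device-malfunction period table
#'
#' @param source Path to a CSV file (`patient_id`, `start_date`, `end_date`,
#'   inclusive dates) or a data frame.
#' @return Validated data frame with `Date` columns.
#' @export
parse_malfunction_table <- function(source) {
  df <- if (is.data.frame(source)) source else {
    utils::read.csv(source, stringsAsFactors = FALSE)
  }
  required <- c("patient_id", "start_date", "end_date")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("malfunction table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$start_date <- as.Date(df$start_date)
  df$end_date <- as.Date(df$end_date)
  if (anyNA(df$start_date) || anyNA(df$end_date)) {
    stop("unparseable date in malfunction table", call. = FALSE)
  }
  if (any(df$start_date > df$end_date)) {
    stop("malfunction period with start_date after end_date", call. = FALSE)
  }
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Assign an actuation to its half-day dose window
#'
#' The day is split at midday into two potential dose windows:
#' `[00:00, 12:00)` is AM and `[12:00, 24:00)` is PM, so 12:00 exactly
#' belongs to PM.
#'
#' @param timestamp POSIXct vector.
#' @return Character vector of `"AM"` / `"PM"`.
#' @export
assign_dose_window <- function(timestamp) {
  stopifnot(inherits(timestamp, "POSIXct"))
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  ifelse(lt$hour < 12, "AM", "PM")
}

#' Build per-patient dose grids from events and malfunction periods
#'
#' For each patient in the follow-up table, lays out the follow-up calendar,
#' marks each half-day window as dosed when at least one actuation falls in
#' it (multiple actuations in one window count as a single dose), masks days
#' inside malfunction periods as unobserved — discarding any events recorded
#' there as spurious — and discards events outside the follow-up window.
#' Patients with zero observed days are excluded with a warning.
#'
#' @param events Parsed event data frame (see [parse_event_log()]).
#' @param malfunctions Malfunction period table (see
#'   [parse_malfunction_table()]), or `NULL` for none.
#' @param followup Data frame `patient_id`, `start_date`, `end_date`
#'   defining each patient's follow-up window.
#' @return Named list of `dose_grid` objects, one per retained patient, each
#'   with fields `patient_id`, `days` (Date), `am_taken`, `pm_taken`,
#'   `observed` (logical) and `n_observed_days`.
#' @export
build_dose_grid <- function(events, malfunctions = NULL, followup) {
  stopifnot(all(c("patient_id", "start_date", "end_date") %in%
                  names(followup)))
  followup$start_date <- as.Date(followup$start_date)
  followup$end_date <- as.Date(followup$end_date)
  if (is.null(malfunctions)) malfunctions <- empty_malfunction_table()

  ev_date <- as.Date(events$timestamp, tz = "UTC")
  ev_window <- if (nrow(events)) assign_dose_window(events$timestamp) else
    character()

  grids <- list()
  n_outside <- 0L
  for (i in seq_len(nrow(followup))) {
    pid <- followup$patient_id[i]
    days <- seq(followup$start_date[i], followup$end_date[i], by = "day")
    nd <- length(days)
    observed <- rep(TRUE, nd)
    mal <- malfunctions[malfunctions$patient_id == pid, , drop = FALSE]
    for (j in seq_len(nrow(mal))) {
      observed[days >= mal$start_date[j] & days <= mal$end_date[j]] <- FALSE
    }
    sel <- events$patient_id == pid
    d <- ev_date[sel]
    w <- ev_window[sel]
    inside <- d >= followup$start_date[i] & d <= followup$end_date[i]
    n_outside <- n_outside + sum(!inside)
    d <- d[inside]; w <- w[inside]
    day_idx <- as.integer(d - followup$start_date[i]) + 1L
    on_masked <- !observed[day_idx]
    if (any(on_masked)) {
      warning(sprintf(
        "patient %s: %d event(s) inside malfunction periods discarded",
        pid, sum(on_masked)), call. = FALSE)
      day_idx <- day_idx[!on_masked]
      w <- w[!on_masked]
    }
    am_taken <- rep(FALSE, nd)
    pm_taken <- rep(FALSE, nd)
    am_taken[unique(day_idx[w == "AM"])] <- TRUE
    pm_taken[unique(day_idx[w == "PM"])] <- TRUE
    n_obs <- sum(observed)
    if (n_obs < 1) {
      warning(sprintf("patient %s has zero observed days; excluded", pid),
              call. = FALSE)
      next
    }
    grids[[pid]] <- new_dose_grid(pid, days, am_taken, pm_taken, observed)
  }
  if (n_outside > 0) {
    warning(sprintf("%d event(s) outside patient follow-up windows discarded",
                    n_outside), call. = FALSE)
  }
  grids
}

new_dose_grid <- function(patient_id, days, am_taken, pm_taken, observed) {
  stopifnot(length(days) == length(am_taken),
            length(days) == length(pm_taken),
            length(days) == length(observed))
  # flags cannot be set on unobserved days
  am_taken[!observed] <- FALSE
  pm_taken[!observed] <- FALSE
  structure(
    list(patient_id = patient_id, days = as.Date(days),
         am_taken = as.logical(am_taken), pm_taken = as.logical(pm_taken),
         observed = as.logical(observed),
         n_observed_days = sum(observed)),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> patient %s: %d days (%d observed), %d doses taken\n",
              x$patient_id, length(x$days), x$n_observed_days,
              sum(x$am_taken) + sum(x$pm_taken)))
  invisible(x)
}

#' Serialize dose grids to a long-format data frame
#'
#' One row per patient-day with columns `patient_id`, `date`, `am_taken`,
#' `pm_taken`, `observed`. [read_dose_grids()] inverts this exactly.
#'
#' @param grids Named list of `dose_grid` objects.
#' @return Long-format data frame.
#' @export
dose_grids_to_df <- function(grids) {
  do.call(rbind, lapply(unname(grids), function(g) {
    data.frame(patient_id = g$patient_id, date = g$days,
               am_taken = g$am_taken, pm_taken = g$pm_taken,
               observed = g$observed, stringsAsFactors = FALSE)
  }))
}

#' Read dose grids back from long-format CSV or data frame
#'
#' @param source Path to CSV written from [dose_grids_to_df()], or the data
#'   frame itself.
#' @return Named list of `dose_grid` objects.
#' @export
read_dose_grids <- function(source) {
  df <- if (is.data.frame(source)) source else {
    utils::read.csv(source, stringsAsFactors = FALSE)
  }
  df$date <- as.Date(df$date)
  to_logical <- function(x) if (is.logical(x)) x else as.logical(x)
  out <- lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$date), , drop = FALSE]
    new_dose_grid(d$patient_id[1], d$date, to_logical(d$am_taken),
                  to_logical(d$pm_taken), to_logical(d$observed))
  })
  out[order(names(out))]
}
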