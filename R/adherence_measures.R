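# Person-level adherence measures over a dose grid.
#
# Implementation measures (dose taking within a day):
#   A  % of prescribed doses taken        = doses_taken / (2 n) * 100
#   B  % of days with zero doses          = d0 / n * 100
#   C  % of days with both doses          = d2 / n * 100
# Persistence measures (treatment intermissions of >= 5 consecutive
# zero-dose days):
#   D  intermissions per 100 study days   = n_intermissions / n * 100
#   E  intermission days per 100 days     = intermission_days / n * 100
# with n = observed ("days with device") days; malfunction days are excluded
# from every numerator and denominator.

MEASURE_NAMES <- c("A", "B", "C", "D", "E")

#' Detect treatment intermissions in a dose grid
#'
#' An intermission is a maximal run of at least `min_days` consecutive
#' zero-dose days. Runs are scanned within contiguous observed segments: a
#' malfunction-masked day terminates a run without counting toward it, so
#' missing data neither fabricates nor extends an intermission. A run still
#' open at the last observed day is returned with `censored = TRUE`.
#'
#' @param grid A `dose_grid`.
#' @param min_days Minimum run length to count as an intermission
#'   (default 5).
#' @return Data frame with `start_day` (1-based follow-up day index),
#'   `duration` (days) and `censored` (logical); zero rows when there is no
#'   intermission.
#' @export
detect_intermissions <- function(grid, min_days = 5L) {
  stopifnot(inherits(grid, "dose_grid"), min_days >= 1)
  if (grid$n_observed_days < 1) {
    stop("grid has no observed days", call. = FALSE)
  }
  zero_dose <- !grid$am_taken & !grid$pm_taken
  last_observed <- max(which(grid$observed))

  out <- list()
  run_start <- NA_integer_
  n_days <- length(grid$days)
  for (i in seq_len(n_days + 1L)) {
    in_run <- i <= n_days && grid$observed[i] && zero_dose[i]
    if (in_run && is.na(run_start)) run_start <- i
    if (!in_run && !is.na(run_start)) {
      run_end <- i - 1L
      dur <- run_end - run_start + 1L
      if (dur >= min_days) {
        out[[length(out) + 1L]] <- data.frame(
          start_day = run_start, duration = dur,
          censored = run_end == last_observed)
      }
      run_start <- NA_integer_
    }
  }
  if (!length(out)) {
    return(data.frame(start_day = integer(), duration = integer(),
                      censored = logical()))
  }
  do.call(rbind, out)
}

#' Compute the five adherence measures for one patient
#'
#' @param grid A `dose_grid` with at least one observed day.
#' @param min_intermission Minimum intermission length in days (default 5).
#' @param include_censored Count an intermission still open at the end of
#'   observation, with its truncated duration, in measures D and E
#'   (default `TRUE`; set `FALSE` to restrict to completed intermissions).
#' @return One-row data frame with `patient_id`, measures `A`-`E`, and the
#'   supporting counts `doses_taken`, `d0`, `d1`, `d2`, `n_observed_days`,
#'   `n_intermissions`, `total_intermission_days`, plus the descriptive
#'   `first_intermission_day` and `first_intermission_duration` (NA when
#'   the patient has no intermission).
#' @export
compute_profile <- function(grid, min_intermission = 5L,
                            include_censored = TRUE) {
  stopifnot(inherits(grid, "dose_grid"))
  n <- grid$n_observed_days
  if (n < 1) {
    stop(sprintf("patient %s has no observed days; profile undefined",
                 grid$patient_id), call. = FALSE)
  }
  obs <- grid$observed
  doses_per_day <- (grid$am_taken + grid$pm_taken)[obs]
  d0 <- sum(doses_per_day == 0)
  d1 <- sum(doses_per_day == 1)
  d2 <- sum(doses_per_day == 2)
  doses_taken <- d1 + 2L * d2

  interm <- detect_intermissions(grid, min_days = min_intermission)
  first_day <- if (nrow(interm)) interm$start_day[1] else NA_integer_
  first_dur <- if (nrow(interm)) interm$duration[1] else NA_integer_
  if (!include_censored && nrow(interm)) {
    interm <- interm[!interm$censored, , drop = FALSE]
  }
  n_int <- nrow(interm)
  int_days <- sum(interm$duration)

  data.frame(
    patient_id = grid$patient_id,
    A = 100 * doses_taken / (2 * n),
    B = 100 * d0 / n,
    C = 100 * d2 / n,
    D = 100 * n_int / n,
    E = 100 * int_days / n,
    doses_taken = doses_taken, d0 = d0, d1 = d1, d2 = d2,
    n_observed_days = n,
    n_intermissions = n_int,
    total_intermission_days = int_days,
    first_intermission_day = first_day,
    first_intermission_duration = first_dur,
    stringsAsFactors = FALSE
  )
}

#' Compute adherence profiles for a whole cohort
#'
#' @param grids Named list of `dose_grid` objects.
#' @inheritParams compute_profile
#' @return Data frame with one row per patient, ordered by `patient_id`.
#' @export
cohort_profiles <- function(grids, min_intermission = 5L,
                            include_censored = TRUE) {
  stopifnot(length(grids) >= 1)
  out <- do.call(rbind, lapply(grids, compute_profile,
                               min_intermission = min_intermission,
                               include_censored = include_censored))
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate every intermission in a cohort
#'
#' @param grids Named list of `dose_grid` objects.
#' @param min_days Minimum intermission length in days (default 5).
#' @return Data frame with `patient_id`, `start_day`, `start_date`,
#'   `duration`, `censored`; one row per intermission.
#' @export
cohort_intermissions <- function(grids, min_days = 5L) {
  out <- lapply(grids, function(g) {
    d <- detect_intermissions(g, min_days = min_days)
    if (!nrow(d)) return(NULL)
    cbind(patient_id = g$patient_id, d,
          start_date = g$days[d$start_day])[, c("patient_id", "start_day",
                                                "start_date", "duration",
                                                "censored")]
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), start_day = integer(),
                      start_date = as.Date(character()),
                      duration = integer(), censored = logical())
  }
  rownames(out) <- NULL
  out
}

#' Assemble the patients x measures matrix for latent-structure analysis
#'
#' @param profiles Data frame of adherence profiles (see
#'   [cohort_profiles()]); requires at least two patients.
#' @return Numeric matrix with one row per patient (rownames =
#'   `patient_id`, sorted) and columns `A`, `B`, `C`, `D`, `E`.
#' @export
cohort_measure_matrix <- function(profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("patient_id", MEASURE_NAMES) %in% names(profiles)))
  if (nrow(profiles) < 2) {
    stop("need at least two profiles to build a measure matrix",
         call. = FALSE)
  }
  if (anyDuplicated(profiles$patient_id)) {
    stop("duplicate patient_id in profiles: ",
         paste(unique(profiles$patient_id[duplicated(profiles$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  profiles <- profiles[order(profiles$patient_id), , drop = FALSE]
  m <- as.matrix(profiles[, MEASURE_NAMES])
  rownames(m) <- profiles$patient_id
  m
}
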