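# Synthetic EMD cohort generator.
#
# Emulates actuation logs from inhaler-mounted electronic monitoring devices
# in a twice-daily ICS cohort: per-archetype dose-taking probabilities,
# treatment intermissions generated by a per-day hazard with durations of at
# least five days, battery-failure missing blocks, and actuation clock times
# concentrated in the 07:00-10:00 and 19:00-22:00 windows.

#' Define a behavioural archetype for the synthetic cohort
#'
#' An archetype describes one stereotyped medication-taking pattern. Outside
#' treatment intermissions, each half-day dose is taken independently with
#' the window's probability; a per-day hazard starts an intermission, during
#' which all dose probabilities are zero. Intermission durations are
#' `5 + Geometric` days so every generated intermission meets the five-day
#' persistence definition used downstream.
#'
#' @param name Archetype label.
#' @param am_dose_prob,pm_dose_prob Probability that the morning / evening
#'   dose is taken on a non-intermission day.
#' @param intermission_start_prob Per-day hazard (outside intermissions) of
#'   beginning an intermission.
#' @param intermission_mean_extra_days Mean of the geometric number of days
#'   added to the 5-day minimum intermission duration.
#' @param extra_actuation_prob Probability that a taken dose is recorded as
#'   two puffs rather than one.
#' @return An object of class `archetype_spec`.
#' @export
archetype_spec <- function(name, am_dose_prob, pm_dose_prob,
                           intermission_start_prob,
                           intermission_mean_extra_days = 5,
                           extra_actuation_prob = 0.1) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  assert_prob(am_dose_prob, "am_dose_prob")
  assert_prob(pm_dose_prob, "pm_dose_prob")
  assert_prob(intermission_start_prob, "intermission_start_prob")
  assert_prob(extra_actuation_prob, "extra_actuation_prob")
  if (!is.numeric(intermission_mean_extra_days) ||
      intermission_mean_extra_days < 0) {
    stop("`intermission_mean_extra_days` must be >= 0", call. = FALSE)
  }
  structure(
    list(name = name,
         am_dose_prob = am_dose_prob,
         pm_dose_prob = pm_dose_prob,
         intermission_start_prob = intermission_start_prob,
         intermission_mean_extra_days = intermission_mean_extra_days,
         extra_actuation_prob = extra_actuation_prob),
    class = "archetype_spec"
  )
}

#' Default poor / moderate / good adherence archetypes
#'
#' Parameters are chosen so that the archetype-wise medians of the
#' percentage of doses taken sit near 16%, 55% and 91% over a ~185-day
#' follow-up, bracketing the adherence levels the typology is meant to
#' separate, with clearly non-overlapping interquartile ranges.
#'
#' @return Named list of three [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  list(
    poor = archetype_spec("poor", am_dose_prob = 0.22, pm_dose_prob = 0.22,
                          intermission_start_prob = 0.035,
                          intermission_mean_extra_days = 7),
    moderate = archetype_spec("moderate", am_dose_prob = 0.62,
                              pm_dose_prob = 0.62,
                              intermission_start_prob = 0.008,
                              intermission_mean_extra_days = 5),
    good = archetype_spec("good", am_dose_prob = 0.93, pm_dose_prob = 0.93,
                          intermission_start_prob = 0.001,
                          intermission_mean_extra_days = 1)
  )
}

#' Default two-arm archetype reweighting
#'
#' Mixture weights per arm that push the control arm towards roughly 36% of
#' doses taken on average and the intervention arm towards roughly 80%,
#' mimicking a reminder-intervention trial. Used when
#' `cohort_config(arm_assignment = TRUE)`.
#'
#' @return Named list with `control` and `intervention` weight vectors.
#' @export
two_arm_weights <- function() {
  list(control = c(poor = 0.55, moderate = 0.35, good = 0.10),
       intervention = c(poor = 0.05, moderate = 0.25, good = 0.70))
}

#' Configure a synthetic EMD cohort
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; identical configuration and seed produce
#'   byte-identical output.
#' @param archetypes Named list of [archetype_spec()] objects.
#' @param archetype_weights Mixture proportions over `archetypes`
#'   (must sum to 1).
#' @param arm_assignment `NULL`/`FALSE` for a single-arm cohort (default);
#'   `TRUE` for a 50/50 two-arm cohort using [two_arm_weights()]; or a named
#'   list of per-arm weight vectors.
#' @param followup_range Min and max follow-up days; per-patient follow-up is
#'   a rounded normal (mean 185, sd 10) truncated to this range, giving a
#'   median near 185 days.
#' @param missing_block_prob Probability a patient has one battery-failure
#'   missing block.
#' @param missing_block_meanlog,missing_block_sdlog Log-normal parameters of
#'   the block length (median 22 days by default).
#' @param missing_block_range Min and max block length in days.
#' @param am_window,pm_window Clock-hour windows in which most actuations
#'   fall.
#' @param window_prob Probability an actuation time is drawn inside its
#'   3-hour window rather than uniformly over the half-day.
#' @param start_date Calendar date of follow-up day 1 (all patients).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, seed,
                          archetypes = default_archetypes(),
                          archetype_weights = NULL,
                          arm_assignment = NULL,
                          followup_range = c(155L, 210L),
                          missing_block_prob = 0.26,
                          missing_block_meanlog = log(22),
                          missing_block_sdlog = 0.9,
                          missing_block_range = c(2L, 122L),
                          am_window = c(7, 10),
                          pm_window = c(19, 22),
                          window_prob = 0.95,
                          start_date = as.Date("2012-03-01")) {
  assert_count(n_patients, "n_patients", min = 1L)
  assert_count(seed, "seed", min = 0L)
  if (!length(archetypes) || !all(vapply(archetypes, inherits, logical(1),
                                         "archetype_spec"))) {
    stop("`archetypes` must be a non-empty list of archetype_spec objects",
         call. = FALSE)
  }
  if (is.null(names(archetypes))) {
    names(archetypes) <- vapply(archetypes, `[[`, character(1), "name")
  }
  if (is.null(archetype_weights)) {
    archetype_weights <- rep(1 / length(archetypes), length(archetypes))
    names(archetype_weights) <- names(archetypes)
  }
  if (length(archetype_weights) != length(archetypes) ||
      abs(sum(archetype_weights) - 1) > 1e-9 || any(archetype_weights < 0)) {
    stop("`archetype_weights` must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (isTRUE(arm_assignment)) arm_assignment <- two_arm_weights()
  if (isFALSE(arm_assignment)) arm_assignment <- NULL
  if (!is.null(arm_assignment)) {
    ok <- is.list(arm_assignment) && length(arm_assignment) >= 2 &&
      !is.null(names(arm_assignment)) &&
      all(vapply(arm_assignment, function(w) {
        length(w) == length(archetypes) && abs(sum(w) - 1) <= 1e-9 &&
          all(w >= 0)
      }, logical(1)))
    if (!ok) {
      stop("`arm_assignment` must be a named list of weight vectors, one ",
           "weight per archetype, each summing to 1", call. = FALSE)
    }
  }
  stopifnot(length(followup_range) == 2, followup_range[1] >= 1,
            followup_range[2] <= 1000,
            followup_range[1] <= followup_range[2])
  assert_prob(missing_block_prob, "missing_block_prob")
  assert_prob(window_prob, "window_prob")
  structure(
    list(n_patients = as.integer(n_patients),
         seed = as.integer(seed),
         archetypes = archetypes,
         archetype_weights = archetype_weights,
         arm_assignment = arm_assignment,
         followup_range = as.integer(followup_range),
         missing_block_prob = missing_block_prob,
         missing_block_meanlog = missing_block_meanlog,
         missing_block_sdlog = missing_block_sdlog,
         missing_block_range = as.integer(missing_block_range),
         am_window = am_window,
         pm_window = pm_window,
         window_prob = window_prob,
         start_date = as.Date(start_date)),
    class = "cohort_config"
  )
}

# Intermission day mask for one patient: per-day hazard starts an episode,
# durations are 5 + Geometric(mean extra) days, truncated at end of follow-up.
sample_intermission_mask <- function(n_days, hazard, mean_extra) {
  mask <- logical(n_days)
  if (hazard <= 0) return(mask)
  p_dur <- 1 / (1 + mean_extra)
  cursor <- 1L
  while (cursor <= n_days) {
    wait <- stats::rgeom(1L, hazard) + 1L  # days until an episode starts
    start <- cursor + wait - 1L
    if (start > n_days) break
    dur <- 5L + stats::rgeom(1L, p_dur)
    end <- min(start + dur - 1L, n_days)
    mask[start:end] <- TRUE
    cursor <- end + 1L
  }
  mask
}

# Clock time (fractional hours) for a vector of doses in one half-day window.
sample_clock_hours <- function(n, window, halfday, window_prob) {
  in_window <- stats::runif(n) < window_prob
  hours <- numeric(n)
  hours[in_window] <- stats::runif(sum(in_window), window[1], window[2])
  hours[!in_window] <- stats::runif(sum(!in_window), halfday[1], halfday[2])
  hours
}

#' Generate a synthetic EMD cohort
#'
#' Produces an actuation event log, a device-malfunction period table and
#' ground-truth archetype labels for a seeded synthetic cohort. Events in
#' malfunction periods are removed via [inject_missingness()], mirroring
#' battery-failure gaps in real device logs.
#'
#' @param config A [cohort_config()] object.
#' @return A list with elements `events` (data frame: `patient_id`,
#'   `timestamp` in ISO 8601 minute precision, `n_actuations`),
#'   `malfunctions` (`patient_id`, `start_date`, `end_date`, inclusive),
#'   `labels` (`patient_id`, `archetype`, `arm`) and `followup`
#'   (`patient_id`, `start_date`, `end_date`, `followup_days`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  arche_names <- names(config$archetypes)

  # Arm and archetype assignment
  if (is.null(config$arm_assignment)) {
    arm <- rep("all", n)
    archetype <- sample(arche_names, n, replace = TRUE,
                        prob = config$archetype_weights)
  } else {
    arms <- names(config$arm_assignment)
    arm <- sample(arms, n, replace = TRUE)
    archetype <- character(n)
    for (a in arms) {
      idx <- which(arm == a)
      if (length(idx)) {
        archetype[idx] <- sample(arche_names, length(idx), replace = TRUE,
                                 prob = config$arm_assignment[[a]])
      }
    }
  }

  # Follow-up duration: rounded truncated normal, median ~185 days
  fu <- round(stats::rnorm(n, mean = 185, sd = 10))
  fu <- pmin(pmax(fu, config$followup_range[1]), config$followup_range[2])

  ev_list <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- config$archetypes[[archetype[i]]]
    n_days <- fu[i]
    interm <- sample_intermission_mask(n_days, spec$intermission_start_prob,
                                       spec$intermission_mean_extra_days)
    am <- stats::runif(n_days) < spec$am_dose_prob & !interm
    pm <- stats::runif(n_days) < spec$pm_dose_prob & !interm
    day <- c(which(am), which(pm))
    win <- rep(c("AM", "PM"), c(sum(am), sum(pm)))
    if (!length(day)) {
      ev_list[[i]] <- NULL
      next
    }
    hours <- numeric(length(day))
    is_am <- win == "AM"
    hours[is_am] <- sample_clock_hours(sum(is_am), config$am_window,
                                       c(0, 12), config$window_prob)
    hours[!is_am] <- sample_clock_hours(sum(!is_am), config$pm_window,
                                        c(12, 24), config$window_prob)
    n_act <- 1L + stats::rbinom(length(day), 1L, spec$extra_actuation_prob)
    ts <- as.POSIXct(config$start_date, tz = "UTC") +
      (day - 1) * 86400 + floor(hours * 60) * 60
    ev_list[[i]] <- data.frame(
      patient_id = ids[i],
      timestamp = ts,
      n_actuations = n_act,
      stringsAsFactors = FALSE
    )
  }
  events <- do.call(rbind, ev_list)
  if (is.null(events)) {
    events <- data.frame(patient_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                         n_actuations = integer(), stringsAsFactors = FALSE)
  }
  events <- events[order(events$patient_id, events$timestamp), , drop = FALSE]
  rownames(events) <- NULL

  followup <- data.frame(
    patient_id = ids,
    start_date = config$start_date,
    end_date = config$start_date + fu - 1,
    followup_days = as.integer(fu),
    stringsAsFactors = FALSE
  )

  masked <- inject_missingness(events, followup, config)

  labels <- data.frame(patient_id = ids, archetype = archetype, arm = arm,
                       stringsAsFactors = FALSE)
  list(events = masked$events, malfunctions = masked$malfunctions,
       labels = labels, followup = followup)
}

#' Remove events falling in device-malfunction periods
#'
#' Samples one battery-failure block per affected patient (length log-normal,
#' median 22 days, truncated to 2-122 days and to the follow-up window) and
#' drops every event whose date falls inside a block, or applies a
#' caller-supplied block table. Consumes the current RNG stream when
#' sampling.
#'
#' @param events Event data frame (`patient_id`, `timestamp`,
#'   `n_actuations`).
#' @param followup Per-patient follow-up table as returned by
#'   [generate_cohort()].
#' @param config A [cohort_config()]; used for block sampling when `blocks`
#'   is `NULL`.
#' @param blocks Optional pre-specified malfunction table (`patient_id`,
#'   `start_date`, `end_date`); must lie within each patient's follow-up.
#' @return List with `events` (filtered) and `malfunctions` (block table).
#' @export
inject_missingness <- function(events, followup, config = NULL,
                               blocks = NULL) {
  if (is.null(blocks)) {
    stopifnot(inherits(config, "cohort_config"))
    has_block <- stats::runif(nrow(followup)) < config$missing_block_prob
    idx <- which(has_block)
    if (length(idx)) {
      len <- round(stats::rlnorm(length(idx), config$missing_block_meanlog,
                                 config$missing_block_sdlog))
      len <- pmin(pmax(len, config$missing_block_range[1]),
                  config$missing_block_range[2])
      len <- pmin(len, followup$followup_days[idx])
      # uniform placement of the block within follow-up
      offset <- floor(stats::runif(length(idx)) *
                        (followup$followup_days[idx] - len + 1))
      blocks <- data.frame(
        patient_id = followup$patient_id[idx],
        start_date = followup$start_date[idx] + offset,
        end_date = followup$start_date[idx] + offset + len - 1,
        stringsAsFactors = FALSE
      )
    } else {
      blocks <- empty_malfunction_table()
    }
  } else {
    blocks <- as.data.frame(blocks)
    blocks$start_date <- as.Date(blocks$start_date)
    blocks$end_date <- as.Date(blocks$end_date)
    m <- match(blocks$patient_id, followup$patient_id)
    if (anyNA(m)) {
      stop("malfunction block for unknown patient", call. = FALSE)
    }
    bad <- blocks$start_date < followup$start_date[m] |
      blocks$end_date > followup$end_date[m] |
      blocks$start_date > blocks$end_date
    if (any(bad)) {
      stop("malfunction block outside the patient's follow-up window",
           call. = FALSE)
    }
  }
  if (nrow(blocks) && nrow(events)) {
    ev_date <- as.Date(events$timestamp, tz = "UTC")
    drop <- rep(FALSE, nrow(events))
    for (j in seq_len(nrow(blocks))) {
      drop <- drop | (events$patient_id == blocks$patient_id[j] &
                        ev_date >= blocks$start_date[j] &
                        ev_date <= blocks$end_date[j])
    }
    events <- events[!drop, , drop = FALSE]
    rownames(events) <- NULL
  }
  list(events = events, malfunctions = blocks)
}

empty_malfunction_table <- function() {
  data.frame(patient_id = character(),
             start_date = as.Date(character()),
             end_date = as.Date(character()),
             stringsAsFactors = FALSE)
}

#' Write cohort artifacts as CSV files
#'
#' Serializes the event log (ISO 8601 minute-precision timestamps),
#' malfunction table, labels and follow-up table of a generated cohort.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- cohort$events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M", tz = "UTC")
  paths <- c(events = file.path(dir, "events.csv"),
             malfunctions = file.path(dir, "malfunctions.csv"),
             labels = file.path(dir, "labels.csv"),
             followup = file.path(dir, "followup.csv"))
  utils::write.csv(ev, paths["events"], row.names = FALSE)
  utils::write.csv(cohort$malfunctions, paths["malfunctions"],
                   row.names = FALSE)
  utils::write.csv(cohort$labels, paths["labels"], row.names = FALSE)
  utils::write.csv(cohort$followup, paths["followup"], row.names = FALSE)
  invisible(paths)
}
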