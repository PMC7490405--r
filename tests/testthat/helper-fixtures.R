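# Shared fixtures and independent oracles for the test suite.

# Build a dose grid directly from per-day logical vectors.
make_grid <- function(am, pm, observed = rep(TRUE, length(am)),
                      patient_id = "T1",
                      start = as.Date("2012-03-01")) {
  days <- seq(start, by = "day", length.out = length(am))
  adhertype:::new_dose_grid(patient_id, days, am, pm, observed)
}

# Grid from a vector of daily dose counts (0, 1 = AM only, 2 = both).
grid_from_doses <- function(doses, ...) {
  make_grid(am = doses >= 1, pm = doses >= 2, ...)
}

# Random dose grid; consumes the caller's RNG stream.
random_grid <- function(n_days, p_dose = 0.4, p_observed = 0.9,
                        patient_id = "R1") {
  make_grid(am = stats::runif(n_days) < p_dose,
            pm = stats::runif(n_days) < p_dose,
            observed = stats::runif(n_days) < p_observed,
            patient_id = patient_id)
}

# Independent brute-force intermission oracle: enumerate every day range,
# keep maximal all-zero-dose runs of observed days of length >= min_days.
oracle_intermissions <- function(grid, min_days = 5) {
  eligible <- !grid$am_taken & !grid$pm_taken & grid$observed
  n <- length(eligible)
  if (!any(grid$observed)) return(NULL)
  last_obs <- max(which(grid$observed))
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < min_days) next
      if (!all(eligible[i:j])) next
      maximal_left <- i == 1 || !eligible[i - 1]
      maximal_right <- j == n || !eligible[j + 1]
      if (maximal_left && maximal_right) {
        out[[length(out) + 1]] <- data.frame(
          start_day = i, duration = j - i + 1, censored = j == last_obs)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start_day = integer(), duration = integer(),
                      censored = logical()))
  }
  do.call(rbind, out)
}

# Independent exhaustive Gini threshold search for a single binary split:
# minimizes the size-weighted sum of child Gini impurities over every
# midpoint between adjacent observed values, honouring a leaf-size floor.
gini_impurity <- function(y) {
  p <- table(y) / length(y)
  1 - sum(p^2)
}

oracle_best_split <- function(x, y, min_leaf = 1) {
  ux <- sort(unique(x))
  if (length(ux) < 2) return(NULL)
  cand <- (head(ux, -1) + tail(ux, -1)) / 2
  best <- NULL
  best_imp <- Inf
  for (t in cand) {
    left <- y[x < t]
    right <- y[x >= t]
    if (length(left) < min_leaf || length(right) < min_leaf) next
    imp <- length(left) * gini_impurity(left) +
      length(right) * gini_impurity(right)
    if (imp < best_imp - 1e-12) {
      best_imp <- imp
      best <- t
    }
  }
  if (is.null(best)) return(NULL)
  list(threshold = best, impurity = best_imp)
}

# Weighted child impurity achieved by a given threshold.
split_impurity <- function(x, y, threshold) {
  left <- y[x < threshold]
  right <- y[x >= threshold]
  length(left) * gini_impurity(left) + length(right) * gini_impurity(right)
}

# Small synthetic cohort processed to profiles, for reuse across tests.
make_processed_cohort <- function(n_patients = 60, seed = 42, ...) {
  co <- generate_cohort(cohort_config(n_patients = n_patients, seed = seed,
                                      ...))
  grids <- suppressWarnings(
    build_dose_grid(co$events, co$malfunctions, co$followup))
  profiles <- cohort_profiles(grids)
  list(cohort = co, grids = grids, profiles = profiles,
       measures = cohort_measure_matrix(profiles))
}
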