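test_that("cohort generation is deterministic for a fixed config and seed", {
  cfg <- cohort_config(n_patients = 15, seed = 101)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # and the serialized form is byte-identical too
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in c("events.csv", "malfunctions.csv", "labels.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_patients = 0, seed = 1), "n_patients")
  expect_error(
    cohort_config(n_patients = 5, seed = 1,
                  archetype_weights = c(0.5, 0.2, 0.2)),
    "sum to 1")
  expect_error(
    archetype_spec("x", am_dose_prob = 1.2, pm_dose_prob = 0.5,
                   intermission_start_prob = 0),
    "probability")
})

test_that("a perfect-adherence archetype yields A = 100 and D = E = 0", {
  perfect <- archetype_spec("perfect", 1, 1, intermission_start_prob = 0)
  cfg <- cohort_config(n_patients = 8, seed = 7,
                       archetypes = list(perfect = perfect),
                       missing_block_prob = 0)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$malfunctions), 0)
  grids <- build_dose_grid(co$events, co$malfunctions, co$followup)
  prof <- cohort_profiles(grids)
  expect_equal(prof$A, rep(100, 8))
  expect_equal(prof$D, rep(0, 8))
  expect_equal(prof$E, rep(0, 8))
})

test_that("coin-flip dosing gives cohort mean A near 50% (binomial check)", {
  half <- archetype_spec("half", 0.5, 0.5, intermission_start_prob = 0)
  cfg <- cohort_config(n_patients = 100, seed = 11,
                       archetypes = list(half = half),
                       missing_block_prob = 0,
                       followup_range = c(200L, 200L))
  co <- generate_cohort(cfg)
  grids <- build_dose_grid(co$events, co$malfunctions, co$followup)
  prof <- cohort_profiles(grids)
  # SE of the cohort mean of A under Binomial(2 * 200 * 100, 0.5)
  se <- 100 * sqrt(0.5 * 0.5 / (2 * 200 * 100))
  expect_lt(abs(mean(prof$A) - 50), 3 * se)
})

test_that("actuation clock times concentrate in the dosing windows", {
  co <- generate_cohort(cohort_config(n_patients = 50, seed = 3,
                                      missing_block_prob = 0))
  hrs <- as.POSIXlt(co$events$timestamp, tz = "UTC")$hour +
    as.POSIXlt(co$events$timestamp, tz = "UTC")$min / 60
  am <- hrs < 12
  expect_gte(mean(hrs[am] >= 7 & hrs[am] < 10), 0.90)
  expect_gte(mean(hrs[!am] >= 19 & hrs[!am] < 22), 0.90)
})

test_that("malfunction blocks mask events and person-days as specified", {
  cfg <- cohort_config(n_patients = 5, seed = 13, missing_block_prob = 0)
  co <- generate_cohort(cfg)
  # no blocks requested -> empty table
  expect_equal(nrow(co$malfunctions), 0)

  # impose one block covering follow-up days 10-12 of the first patient
  start <- co$followup$start_date[1]
  blocks <- data.frame(patient_id = co$followup$patient_id[1],
                       start_date = start + 9, end_date = start + 11)
  masked <- inject_missingness(co$events, co$followup, blocks = blocks)
  ev <- masked$events
  ev_days <- as.Date(ev$timestamp, tz = "UTC")
  hit <- ev$patient_id == blocks$patient_id &
    ev_days >= blocks$start_date & ev_days <= blocks$end_date
  expect_equal(sum(hit), 0)

  # a 22-day block in a 185-day follow-up leaves 163 observed person-days
  fu <- data.frame(patient_id = "P1", start_date = start,
                   end_date = start + 184, followup_days = 185L)
  b22 <- data.frame(patient_id = "P1", start_date = start + 50,
                    end_date = start + 71)
  g <- build_dose_grid(
    data.frame(patient_id = character(),
               timestamp = as.POSIXct(character(), tz = "UTC"),
               n_actuations = integer()),
    b22, fu)
  expect_equal(g[["P1"]]$n_observed_days, 163)

  # blocks outside follow-up are a configuration error
  bad <- data.frame(patient_id = "P1", start_date = start + 180,
                    end_date = start + 200)
  expect_error(inject_missingness(co$events, fu, blocks = bad),
               "outside")
})

test_that("default archetypes produce separated adherence distributions", {
  pc <- make_processed_cohort(n_patients = 150, seed = 21)
  arche <- pc$cohort$labels$archetype[match(pc$profiles$patient_id,
                                            pc$cohort$labels$patient_id)]
  iqr <- t(vapply(split(pc$profiles$A, arche), stats::quantile, numeric(2),
                  probs = c(0.25, 0.75)))
  iqr <- iqr[order(iqr[, 1]), ]
  # upper quartile of each archetype below lower quartile of the next
  expect_true(all(iqr[-nrow(iqr), 2] < iqr[-1, 1]))
})

test_that("the two-arm option produces a marked arm difference in A", {
  cfg <- cohort_config(n_patients = 150, seed = 31, arm_assignment = TRUE)
  co <- generate_cohort(cfg)
  grids <- suppressWarnings(
    build_dose_grid(co$events, co$malfunctions, co$followup))
  prof <- cohort_profiles(grids)
  s <- summarize_cohort(grids, prof, co$labels)
  expect_true(s$arm_mean_pct_doses_taken[["intervention"]] >
                s$arm_mean_pct_doses_taken[["control"]] + 20)
})
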