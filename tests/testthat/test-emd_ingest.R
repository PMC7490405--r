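test_that("event logs parse, sort, and reject malformed rows", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,timestamp,n_actuations",
               "P2,2012-03-05T19:30,1",
               "P1,2012-03-02T08:00,2",
               "P1,2012-03-01T07:15,1"), f)
  ev <- parse_event_log(f)
  expect_equal(ev$patient_id, c("P1", "P1", "P2"))
  expect_true(!is.unsorted(ev$timestamp[ev$patient_id == "P1"]))
  expect_equal(ev$n_actuations, c(1L, 2L, 1L))

  writeLines("patient_id,timestamp,n_actuations", f)
  expect_equal(nrow(parse_event_log(f)), 0)

  writeLines(c("patient_id,timestamp,n_actuations",
               "P1,2012-03-01T07:15,1",
               "P1,not-a-date,1"), f)
  expect_error(parse_event_log(f), "line\\(s\\) 2")

  writeLines(c("patient_id,when", "P1,2012-03-01"), f)
  expect_error(parse_event_log(f), "missing required column")
  unlink(f)
})

test_that("dose windows split the day at midday with a half-open boundary", {
  ts <- as.POSIXct(c("2012-03-01 00:00", "2012-03-01 07:30",
                     "2012-03-01 11:59", "2012-03-01 12:00",
                     "2012-03-01 23:59"), tz = "UTC")
  expect_equal(assign_dose_window(ts), c("AM", "AM", "AM", "PM", "PM"))
})

test_that("multiple actuations in one window collapse to a single dose", {
  fu <- data.frame(patient_id = "P1", start_date = as.Date("2012-03-01"),
                   end_date = as.Date("2012-03-03"))
  ev <- parse_event_log(data.frame(
    patient_id = "P1",
    timestamp = c("2012-03-01T07:00", "2012-03-01T07:01",
                  "2012-03-01T19:30"),
    n_actuations = c(1, 1, 2)))
  g <- build_dose_grid(ev, NULL, fu)[["P1"]]
  expect_true(g$am_taken[1] && g$pm_taken[1])
  expect_equal(sum(g$am_taken) + sum(g$pm_taken), 2)  # 2 doses, not 4
  expect_true(all((g$am_taken + g$pm_taken) %in% 0:2))
})

test_that("events on masked days are discarded and flags stay false", {
  fu <- data.frame(patient_id = "P1", start_date = as.Date("2012-03-01"),
                   end_date = as.Date("2012-03-10"))
  mal <- data.frame(patient_id = "P1", start_date = as.Date("2012-03-04"),
                    end_date = as.Date("2012-03-06"))
  ev <- parse_event_log(data.frame(
    patient_id = "P1", timestamp = "2012-03-05T09:00", n_actuations = 1))
  expect_warning(g <- build_dose_grid(ev, mal, fu), "malfunction")
  g <- g[["P1"]]
  expect_false(any(g$am_taken[4:6]) || any(g$pm_taken[4:6]))
  expect_equal(g$n_observed_days, 7)
})

test_that("events outside follow-up are discarded with a warning", {
  fu <- data.frame(patient_id = "P1", start_date = as.Date("2012-03-01"),
                   end_date = as.Date("2012-03-10"))
  ev <- parse_event_log(data.frame(
    patient_id = "P1",
    timestamp = c("2012-02-28T08:00", "2012-03-02T08:00"),
    n_actuations = 1))
  expect_warning(g <- build_dose_grid(ev, NULL, fu), "outside")
  expect_equal(sum(g[["P1"]]$am_taken), 1)
})

test_that("a fully masked patient is excluded with a warning", {
  fu <- data.frame(patient_id = "P1", start_date = as.Date("2012-03-01"),
                   end_date = as.Date("2012-03-05"))
  mal <- data.frame(patient_id = "P1", start_date = as.Date("2012-03-01"),
                    end_date = as.Date("2012-03-05"))
  ev <- parse_event_log(data.frame(patient_id = character(),
                                   timestamp = character(),
                                   n_actuations = integer()))
  expect_warning(g <- build_dose_grid(ev, mal, fu), "zero observed days")
  expect_equal(length(g), 0)
})

test_that("person-days are conserved between observed and masked", {
  pc <- make_processed_cohort(n_patients = 40, seed = 17)
  total_calendar <- sum(pc$cohort$followup$followup_days)
  observed <- sum(vapply(pc$grids, function(g) g$n_observed_days,
                         numeric(1)))
  masked <- sum(vapply(pc$grids, function(g) sum(!g$observed), numeric(1)))
  expect_equal(observed + masked, total_calendar)
})

test_that("dose grids round-trip through long-format CSV", {
  pc <- make_processed_cohort(n_patients = 10, seed = 23)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(dose_grids_to_df(pc$grids), f, row.names = FALSE)
  back <- read_dose_grids(f)
  expect_identical(names(back), names(pc$grids))
  expect_equal(back, pc$grids)
  unlink(f)
})
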