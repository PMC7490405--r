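#!/usr/bin/env Rscript
# Step 2 — ingest the event log and compute the five adherence measures.
#
# Parses the CSV artifacts from step 1, builds per-patient half-day dose
# grids with malfunction masking, and computes the person-level measures:
# A % doses taken, B % zero-dose days, C % both-dose days, D intermissions
# per 100 days, E intermission days per 100 days.

suppressPackageStartupMessages(library(adhertype))

indir <- "results/cohort"
events <- parse_event_log(file.path(indir, "events.csv"))
malf <- parse_malfunction_table(file.path(indir, "malfunctions.csv"))
followup <- utils::read.csv(file.path(indir, "followup.csv"))
labels <- utils::read.csv(file.path(indir, "labels.csv"))

grids <- suppressWarnings(build_dose_grid(events, malf, followup))
profiles <- cohort_profiles(grids)
intermissions <- cohort_intermissions(grids)
s <- summarize_cohort(grids, profiles, labels)

utils::write.csv(profiles, "results/profiles.csv", row.names = FALSE)
utils::write.csv(intermissions, "results/intermissions.csv",
                 row.names = FALSE)
utils::write.csv(dose_grids_to_df(grids), "results/dose_grids.csv",
                 row.names = FALSE)

cat(sprintf("person-days: %d total, %d missing (%d%%), %d analyzed\n",
            s$person_days$total, s$person_days$missing,
            s$person_days$pct_missing, s$person_days$analyzed))
cat(sprintf("%d%% of patients (n = %d) had >= 1 treatment intermission\n",
            s$pct_with_intermission, s$n_with_intermission))
cat(sprintf("first intermission: median day %.0f, median duration %.0f days\n",
            s$median_first_intermission_day,
            s$median_first_intermission_duration))
cat(sprintf("cohort mean %% doses taken: %.1f\n", s$mean_pct_doses_taken))
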