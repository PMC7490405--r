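# adhertype

A data-driven typology of preventer-medication adherence from electronic
monitoring device (EMD) inhaler logs.

Asthma preventer (inhaled corticosteroid) adherence is usually reported as a
single percentage, which hides clinically distinct behaviours: skipping one
of the two daily doses, taking drug holidays of a week or more, or stopping
outright. `adhertype` is for biostatisticians and respiratory-health
researchers working with timestamped actuation logs from inhaler-mounted
EMDs in twice-daily dosing cohorts. It implements the complete path from
raw event log to an interpretable behavioural typology:

1. **Dose grids.** Each actuation is assigned to a half-day window
   (`[00:00,12:00)` AM, `[12:00,24:00)` PM); one or more puffs in a window
   is one dose. Days inside declared device-malfunction periods are masked
   and excluded from all denominators.
2. **Five adherence measures** per patient, with `n` observed days and
   `d0/d1/d2` days with 0/1/2 doses:
   - A = 100·(d1 + 2·d2)/(2n) — % of prescribed doses taken
   - B = 100·d0/n — % of days with zero doses
   - C = 100·d2/n — % of days with both doses
   - D = 100·k/n — treatment intermissions per 100 study days
   - E = 100·t/n — intermission days per 100 study days

   where an *intermission* is a maximal run of ≥5 consecutive zero-dose
   days (k runs, t total days), scanned within observed segments.
3. **Latent structure.** PCA of the patients × 5 matrix under three scaling
   regimes (zero-centering, unit variance, min–max), retaining the smallest
   component count explaining ≥95% of variance.
4. **Cluster typology.** k-means (25 random initialisations) on the
   retained scores; k chosen from the within-group sum-of-squares scree
   curve by an automated elbow rule; cluster stability assessed on 1,000
   bootstrap resamples via best-match Jaccard similarity, with a cluster
   *dissolved* in a replicate when its Jaccard < 0.5. The scaling regime
   with the most stable clusters wins, and clusters are numbered 1..k by
   ascending median of measure A.
5. **Surrogate tree.** Per measure, a shallow CART (≥20 patients to split,
   ≥6 per leaf, ≤2 split levels, cost-complexity pruned by seeded
   label-stratified 10-fold CV) is fit against the cluster labels on a 70%
   training partition; the measure with the best accuracy on a 15%
   validation partition becomes the surrogate, reported with its confusion
   matrix and accuracy (trace/total) on the final 15% test partition.

Because event-level EMD trial data are not publicly deposited, the package
ships a seeded synthetic-cohort generator (`generate_cohort()`) emulating a
two-arm twice-daily ICS cohort — poor/moderate/good adherence archetypes,
≥5-day intermissions from a per-day hazard, battery-failure missing blocks
(median 22 days), and actuation clock times concentrated 07:00–10:00 and
19:00–22:00 — so the entire pipeline is testable and reproducible without
patient records.

## Worked example

```r
library(adhertype)

cfg <- default_pipeline_config(n_patients = 211, seed = 20201)
res <- run_pipeline(cfg)
#> simulated cohort: 211 patients, 41219 events
#> profiles computed: n = 211, 63% with >=1 intermission
#> scaling 'center_only' selected (mean Jaccard 1.000); k = 3 clusters
#> best surrogate measure: A; test accuracy 100.0% (n = 32)

res$summary$person_days
#> $total 38933  $missing 2005  $analyzed 36928  $pct_missing 5

print(res$surrogate$trees[["A"]])
#> <tree_model> measure A, pruning cp = 0
#> if A < 76.2:
#>   if A < 35.06:
#>     predict cluster 1
#>   else (A >= 35.06):
#>     predict cluster 2
#> else (A >= 76.2):
#>   predict cluster 3
```

Reading the output: the cohort's 38,933 person-days lose 5% to
device-malfunction masking; the five measures collapse onto a dominant
adherence axis (two components pass the 95% rule); the scree elbow finds
three clusters under every scaling regime, all perfectly stable over 1,000
bootstrap replicates; and the percentage of doses taken (measure A) alone
reproduces the three-cluster assignment out of sample, with data-driven
thresholds near 35% and 76% separating poor, moderate and good adherence.

The same pipeline can be read step by step in `analysis/01_simulate.R`
through `analysis/05_tree.R`, which write their tables under `results/`.
To run on real data instead of the generator, point
`config$input` at `events.csv`, `malfunctions.csv` and `followup.csv`
files (column layouts in `?parse_event_log`, `?parse_malfunction_table`).

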