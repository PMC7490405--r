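---
title: "Methods: a data-driven typology of inhaler adherence from EMD logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a data-driven typology of inhaler adherence from EMD logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhertype)
```

## The problem

Electronic monitoring devices (EMDs) mounted on preventer inhalers record a
timestamp for every actuation (puff). For a patient prescribed a twice-daily
inhaled corticosteroid, that log contains far more behavioural information
than the single "percent adherence" number most studies report: whether
doses are skipped singly or in long runs, whether both daily doses or only
one are taken, and whether therapy is interrupted for days at a time and
then re-initiated. `adhertype` turns raw actuation logs into a
multidimensional typology of medication-taking behaviour, and then asks
whether a single measure can stand in for the full typology in practice.

The pipeline has five stages, each exposed as ordinary functions so any
stage can be run, inspected or replaced in isolation:

1. **Ingestion** — actuation events to per-patient half-day *dose grids*.
2. **Adherence measures** — five person-level summaries spanning
   implementation and persistence.
3. **Latent structure** — PCA of the measures under three scaling regimes.
4. **Cluster typology** — k-means on the retained component scores, with
   the cluster count chosen from the within-group sum-of-squares curve and
   stability assessed by bootstrap Jaccard similarity.
5. **Surrogate tree** — a shallow, pruned CART per measure, selecting the
   single measure that best predicts cluster membership out of sample.

## Dose definition and ingestion

A *dose* is one or more actuations within a 12-hour half-day window. The
day is split at midday with half-open windows `[00:00, 12:00)` (AM) and
`[12:00, 24:00)` (PM), so a 12:00 actuation is a PM dose; the convention is
fixed because boundary behaviour must be deterministic even though, in
practice, almost all actuations fall 07:00–10:00 or 19:00–22:00. Multiple
actuations within one window count as a single dose, so a day contributes
0, 1 or 2 doses regardless of puff count.

Device-malfunction periods (battery failures declared in the device log)
are masked as *unobserved*: those days are excluded from every numerator
and denominator, and any event recorded inside a declared malfunction block
is treated as spurious and discarded with a warning. Events outside a
patient's follow-up window are likewise discarded with a warning — the
follow-up window comes from cohort metadata, not from the first/last event,
so a silent tail of missed doses counts as non-adherence rather than
vanishing from the denominator. A patient whose entire follow-up is masked
is excluded. Person-days are conserved by construction: observed plus
masked days equal the raw calendar, a property the test suite checks.

## The five measures

With `n` observed days ("days with device"), `d0/d1/d2` the counts of days
with 0/1/2 doses, and intermissions defined below:

* **A** — % of prescribed doses taken: `100 (d1 + 2 d2) / (2n)`
* **B** — % of days with zero doses: `100 d0 / n`
* **C** — % of days with both doses: `100 d2 / n`
* **D** — treatment intermissions per 100 study days: `100 k / n`
* **E** — days spent in intermission per 100 study days: `100 t / n`

A *treatment intermission* is a maximal run of at least 5 consecutive
zero-dose days; `k` is the number of such runs and `t` their total
duration. Runs are scanned **within contiguous observed segments**: a
masked day terminates a run without counting toward it, so missing data can
neither fabricate nor extend an intermission. This is the conservative
reading of removing malfunction periods from the data; the alternative
(bridging runs across masked gaps) would assert doses were missed on days
nobody observed.

A run still open at the last observed day is returned as *censored* and is
counted in D and E with its truncated duration by default. The measures are
summaries of the observation window, and dropping censored runs would
understate non-persistence for exactly the least persistent patients (a
never-dosing patient would otherwise score D = E = 0). The
`include_censored = FALSE` switch provides the stricter
completed-runs-only reading.

Two identities follow algebraically and are enforced as property tests
across randomly generated grids: `A = (100 − B + C) / 2` (each day
contributes `1 − [d0] + [d2]` doses out of 2) and `E ≥ 5 D` (every
intermission contributes at least 5 days). Intermission detection is also
tested against an independent brute-force scan over all day ranges.

Time to first intermission and first-intermission duration are computed as
descriptive outputs only; they are not clustering inputs.

## Scaling regimes and PCA

PCA is sensitive to the relative magnitudes of the inputs, so three
pre-processing regimes are compared: zero-centering only, unit-variance
scaling, and min–max scaling to `[0, 1]`. Unit-variance scaling divides by
the **population** (divide-by-n) standard deviation; because the factor
`sqrt((n−1)/n)` is common to all columns, the choice between population and
sample SD does not change component directions, variance fractions, or any
downstream clustering — only the numeric scale of the scores. A
`denominator = "variance"` option divides by the variance instead, for the
occasionally seen convention in which "unit variance" is read literally as
variance division.

The number of retained components is the smallest count explaining at
least 95% of the variance. Because the identity `A = (100 − B + C)/2` makes
the five measures exactly rank-deficient, the last component always carries
(numerically) zero variance; in practice the first component — a general
adherence axis on which A and C load positively and B, D, E negatively —
dominates, and two components pass the 95% rule on synthetic cohorts.
Component signs are arbitrary in PCA, so each component is oriented to make
measure A load non-negatively; loadings are additionally reported as
variable–component correlations (bounded in ±1), the form conventionally
tabulated. Clustering consumes the scores of the retained components only,
since the component count is fixed before clustering in this design.

## Cluster typology and stability

k-means is run with 25 random initialisations per fit, keeping the lowest
within-group sum of squares (WSS). The WSS curve over k = 1..15 is the
scree input to cluster-count selection. Visual elbow reading is automated
for reproducibility: after min–max normalizing both axes, the selected k
maximizes the perpendicular distance to the chord joining the curve's
endpoints; ties break toward smaller k, a flat curve returns k = 1 with a
warning, and a `k_override` preserves analyst judgement.

Stability is assessed by resampling patients with replacement 1,000 times,
re-clustering each resample (also with 25 initialisations), and matching
every full-sample cluster — restricted to patients present in the
resample — to the resample cluster with the highest Jaccard similarity on
unique patient identifiers. A cluster *dissolves* in a replicate when that
best-match similarity falls below 0.5; per-cluster mean Jaccard and
dissolution rates summarize the replicates. The scaling regime whose
clusters have the highest mean Jaccard wins, with ties broken by lower mean
dissolution rate and then by method order.

Clusters are finally renumbered 1..k by ascending within-cluster median of
measure A, so cluster 1 is always the poorest-adherence group; ties break
by cluster size, descending.

All randomness flows from one master seed expanded into named per-stage
streams (`stage_seeds()`), so individual stages can be re-run in isolation
without disturbing end-to-end reproducibility.

## The surrogate tree

Patients are split 70/15/15 into training, validation and test partitions
(uniform, unstratified, seeded; partition sizes are nearest-integer
allocations with the remainder to training, so n = 211 gives 147/32/32).
One CART is grown per measure on the training partition, with splits
minimizing Gini impurity under the protocol constraints: at least 20
patients at a node to consider a split, at least 6 at any leaf, and at most
two levels of splits ("height 2" in the idiom of the original tree
software — at most 4 leaves; this is configurable). The tree engine is
rpart; thresholds are midpoints between adjacent observed values, and with
one continuous predictor the greedy search is exhaustive (an equivalence
the suite verifies against an independent exhaustive Gini search at depth
1).

The pruning complexity parameter is chosen by 10-fold cross-validation
over the nested cost-complexity sequence, minimizing cross-validated
misclassification. Fold assignment is seeded and label-stratified — a
robustness choice for small cohorts where unstratified folds can lose an
entire class; it does not change the estimand. Ties in CV error go to the
simpler (more pruned) candidate.

The measure whose tree attains the best validation accuracy becomes the
surrogate (ties break in measure order A–E), and the final report is that
tree's confusion matrix and accuracy (trace over total) on the untouched
test partition. A two-way `c(train = 0.7, test = 0.3)` split mode exists
for protocols that skip the validation stage; the three-way protocol is the
primary one, as it is the one consistent with a 32-patient test partition
at n = 211.

## The synthetic cohort generator

No EMD trial dataset is public at the event level, so the package ships a
seeded generator whose defaults are fixed once to emulate the statistical
structure such trials report, and which doubles as the ground-truth source
for parameter-recovery testing:

* **Archetypes.** Three behavioural archetypes (poor / moderate / good)
  with per-window dose probabilities 0.22/0.22, 0.62/0.62 and 0.93/0.93,
  per-day intermission hazards 0.035, 0.008 and 0.001, and mean intermission
  durations 12, 10 and 6 days. Over a ~185-day follow-up these put the
  archetype medians of measure A near 16%, 55% and 91% — the adherence
  levels the typology should separate — with non-overlapping interquartile
  ranges (verified by simulation in the suite).
* **Intermissions.** A per-day hazard starts an episode; durations are
  `5 + Geometric(mean extra)` days so every generated episode meets the
  5-day definition; dose probabilities are zero inside an episode. The
  hazard formulation imposes no trajectory shape, and archetype parameters
  are time-constant — the generator does not model within-person behaviour
  change, which is out of scope for a study-period-aggregated typology.
* **Follow-up.** Rounded normal, mean 185, sd 10, truncated to 155–210
  days: median ≈ 185, IQR ≈ 176–190.
* **Missingness.** 26% of patients receive one battery-failure block;
  block length is log-normal with median 22 days (sdlog 0.9, IQR ≈ 11–43),
  truncated to 2–122 days, placed uniformly within follow-up. This yields
  ≈5% missing person-days at the default cohort size.
* **Clock times.** With probability 0.95 an actuation time is uniform in
  the 07:00–10:00 (AM) or 19:00–22:00 (PM) window, else uniform over its
  half-day; ≥90% of actuations therefore fall inside the 3-hour windows.
  Timestamps are serialized in ISO 8601 at minute precision — sufficient
  for half-day window assignment. All patients share one start date; the
  analysis is invariant to calendar placement.
* **Arms.** An optional two-arm mode reweights the archetype mixture per
  arm (control ≈ 55/35/10, intervention ≈ 5/25/70 percent
  poor/moderate/good) to emulate a reminder-intervention trial in which
  control patients take roughly 36% and intervention patients roughly 80%
  of doses. It is off by default; arm comparisons are descriptive only.

What the generator does **not** emulate: dose dumping (rapid repeated
actuation before clinic visits), technique-dependent dose quality,
seasonality or behaviour change over time, and clinically triggered
re-initiation. Passing tests on synthetic cohorts therefore demonstrate
that the pipeline recovers planted structure of this idealized kind; they
cannot certify behaviour on real logs with artefacts outside the model.

## Numerical choices and degenerate inputs

* WSS curves are monotone non-increasing up to optimizer tolerance
  (1e−8); a k whose fit breaks monotonicity is refitted with 4× the
  initialisations.
* `k` equal to the number of distinct points yields the exact
  zero-within-scatter solution directly; `k` beyond it is an error.
* Jaccard of two empty sets is defined as 0; bootstrap matching uses
  unique patients, not resample multiplicity.
* Constant measure columns are errors under unit-variance and min–max
  scaling (the transform is undefined), and a constant predictor yields a
  root-only majority-class tree.
* Zero-spread, fewer-rows-than-two, empty-partition and zero-bootstrap
  inputs all fail fast with descriptive errors rather than propagating NaN.

## Problem sizes used in the shipped analyses

The `analysis/` drivers and the acceptance script run the full protocol —
211 patients, k = 1..15, 25 initialisations, 1,000 bootstrap replicates per
scaling regime — which completes in well under a minute. The test suite
exercises parameter recovery and surrogate selection on twenty seeded
200-patient cohorts and stability calibration on 200-replicate bootstraps;
these sizes give the binomial headroom the pass criteria need (e.g. ≥18/20
runs) while keeping the suite fast.

## Known limitations

* The typology aggregates over the whole observation window; patients who
  change behaviour mid-study are summarized by their average pattern.
* An 11:30 + 12:30 actuation pair counts as both daily doses despite the
  short spacing; no inter-dose-interval quality measure is computed, as
  actuations concentrate tightly in the morning and evening windows.
* Elbow selection is a deterministic stand-in for a judgement call; for
  curves without a clear knee the override should be used deliberately.
* The surrogate tree is deliberately univariate; it bounds what one
  measure can recover of the multi-measure typology and is not a general
  classifier.
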