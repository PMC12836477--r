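---
title: "Digital phenotyping of mobility and app use: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital phenotyping of mobility and app use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digiphen)
```

## The problem this package addresses

Depression and anxiety are frequently missed in routine care, and passively
collected smartphone data — where a person goes and how they use their phone
— captures behavioral correlates of these conditions (reduced locational
variability, altered phone-use rhythms) without burdening the participant.
`digiphen` implements a complete digital-phenotyping analysis for this
setting: it turns raw location samples and foreground app events into
per-participant behavioral markers, labels a cohort as symptomatic or
asymptomatic from clinical information, evaluates how well the markers
classify symptom status under nested cross-validation, and explains the
trained models with exact Shapley values. Because raw clinical streams of
this kind cannot be shared, the package also ships a synthetic cohort
generator that emulates the raw streams with a *plantable* group difference,
so every stage of the pipeline can be validated against known ground truth.

## Behavioral markers

### Location

All distances are haversine distances on a sphere of radius 6,371,000 m,
which is accurate to well under a meter at the 150-m scales involved.

**Stay points.** A stay point is an episode in which the participant remains
within 150 m of an anchor sample for at least 30 minutes. The detector is
the classic sequential scan from GPS mobility mining: anchor the window at
sample *i*, advance *j* while sample *j* is within 150 m of the anchor, and
when the window spans ≥ 30 minutes emit its centroid and restart after it;
otherwise slide the anchor forward one sample. The duration bound is
*inclusive* — a dwell of exactly 30 minutes counts — applied uniformly to
stay points and trajectories, because the trajectory rule is stated
inclusively ("totaling at least 30 min").

**Unique places.** Repeated visits to the same physical location are
recognized by greedy sequential centroid linkage: each stay point, in
temporal order, joins the first existing place whose running centroid lies
within 150 m, else founds a new place. This is deterministic given input
order and cannot split a place that is visited repeatedly with GPS jitter
well below the link radius.

**Home.** Places are ranked by total dwell time intersected with the
nightly 00:00–05:00 local window; among the top three, home is the place
with the most visits. The night window re-uses the app-feature night
definition because no separate definition exists for location; a
sunset-based window would change little at the latitudes the defaults
emulate but is not implemented.

**Trajectories.** The sample runs strictly between consecutive stay-point
windows (plus the runs before the first and after the last stay point,
whose status is ambiguous in the source description; including them is the
monotone-safe choice) become trajectories iff they contain ≥ 20 samples
spanning ≥ 30 minutes. Both conditions are required; a 35-minute trip
sampled every 10 minutes fails on points alone.

**Per-day averages** divide totals by the number of local calendar days
with at least one location sample (observed days, not the enrollment
window): this matches how data availability is counted for inclusion.

### App use

Sessions are split at local midnight before any per-day statistic, so no
session is counted on two days and total duration is conserved. Night
membership (00:00–05:00 local) is decided by the opening timestamp —
applied per midnight-split piece — and a night session is counted whole,
so a 04:55–05:20 session contributes its full 25 minutes to the night
total. Frequency counts session *openings* per observed app day; duration
is computed per day and then averaged, with the *sum* statistic counting
category-free days as zero and the *mean* statistic averaging only over
days on which the category was used (this is what makes the worked
two-day example give 1.5 and 1.0 minutes respectively). One consequence
worth knowing: the night *mean* duration can exceed the all-day mean (one
long night session among short daytime sessions), so the night ≤ all-day
ordering is an invariant of the frequencies and duration sums only.

**Addiction score.** The fraction of consecutive 20-minute intervals of an
observation window that overlap at least one session. The pipeline scores
each observed day over the full local calendar day (72 intervals) and
averages across days; the narrower windows used in worked examples can be
passed explicitly. A fixed full-day window was chosen over first-to-last
use because it is reproducible and does not reward sparse usage patterns
with inflated denominators. This score captures habitual checking, but it
has no validated mapping onto clinical addiction instruments.

## Cohort labeling and inclusion

A participant is **symptomatic** iff they carry at least one depressive or
anxiety disorder diagnosis, or IDS > 13, or BAI > 9 — both strict
inequalities, as printed; a participant at IDS = 13 and BAI = 9 with no
diagnosis is asymptomatic. Inclusion requires at least 7 observed days of
*each* stream ("fewer than 7 days of both" is parsed as: excluded iff
either stream falls short, which matches the data-quality purpose of the
rule), and excludes iOS devices (no app logging) and participants with no
data at all. Sex is encoded female = 1. Exclusions are logged with reasons
(`no_data` > `ios` > `insufficient_days`, applied in that precedence).

## The classification experiment

The experiment is a stratified 5-fold outer split; within each split:

1. **Preprocessing** is fit on the training partition only: per-feature
   means (for imputing missing values in train *and* test) and min–max
   ranges (train min → 0, max → 1; test values are not clipped and may
   leave `[0, 1]`; constant features map to 0).
2. **Feature selection** (digital features only) is Boruta: each iteration
   appends an independently permuted shadow copy of every feature, fits a
   random forest, and records a hit for features beating the best shadow;
   after 100 iterations, two-sided exact binomial tests against p = 0.5
   with Bonferroni correction over features confirm or reject. Tentative
   features are not selected. If a split confirms nothing, the single
   most-hit feature is used so the cell still has a model. A `fixed` mode
   replaces selection with one named feature (default the total trajectory
   count), mirroring a post-hoc simplification to the most stable feature
   — note that choosing that feature from whole-data stability is itself
   mildly leaky, which is why this is an explicit mode, never a default.
3. **Tuning** is grid search with stratified 10-fold inner CV maximizing
   AUROC, ties resolved to the earliest grid row. Default grids (the
   source analysis does not state its grids): elastic net — penalty
   strength λ ∈ {0.01, 0.1, 1, 10} × mixing α ∈ {0.1, 0.5, 0.9}; random
   forest — trees ∈ {100, 500}, depth ∈ {∞, 3, 5}, min leaf ∈ {1, 5}.
4. **Evaluation** on the held-out partition: AUROC by the rank statistic
   with average ranks for ties (a constant score gives exactly 0.5),
   accuracy, balanced accuracy, and per-class precision/recall/F1 at a
   0.5 threshold with the 0-on-zero-division convention. The dummy
   baseline scores a constant 0.5 and draws its class labels from a
   seeded uniform stream — this reconciles an exactly-0.5 AUROC with
   non-trivial F1 values.

Metrics are aggregated across the five folds by median and range. Three
feature sets are evaluated: demographics (age, sex, years of education),
digital phenotyping, and their combination. Every stochastic component
(folds, shadows, forests, dummy labels) derives its seed from the single
experiment seed, so a re-run reproduces the report exactly, and nothing on
the training side of a split ever reads test labels (verified by a canary
test that corrupts them).

## Model explanation

Shapley values attribute a prediction to features using the marginal
(interventional) expectation: the value of a coalition is the mean model
output over a background set with the coalition's features pinned to the
instance. With the few features the final models use, all `2^p` coalitions
are enumerated exactly (up to 15 features; a seeded permutation sampler
takes over beyond that), so efficiency, null-feature and symmetry hold to
numerical precision, and for linear scores the attribution reduces to
`w_i (x_i − mean(background_i))`. The background is the training fold of
the explained model; the explained quantity is the predicted probability
of the symptomatic class. The long-format export (instance, feature,
feature value, attribution) is exactly what a beeswarm plot is drawn
from, and the sign of each feature's value–attribution rank correlation
is the "direction" one reads off such a plot.

## What the generator emulates — and what it does not

Each synthetic participant receives a planted group with an expected
daily movement rate (defaults: 2/day symptomatic vs 4/day asymptomatic),
a set of places on a jittered grid, demographics, clinical scores drawn
from group-specific truncated normals (symptomatic: IDS ~ N(21.63, 8.40),
BAI ~ N(11.00, 6.35), with ~35% carrying a diagnosis and the rest
re-drawn until they clear a threshold; asymptomatic: IDS ~ N(6.22, 3.59)
truncated at 13, BAI ~ N(2.84, 2.50) truncated at 9), and 4–43 days of
coverage so the 7-day filter has something to do. Days go missing whole,
independently per stream, with probability 0.05. A configurable fraction
(10%) is assigned iOS. Location is sampled every 10 minutes while
stationary and every 60 seconds while moving; dwell jitter has SD 10 m
with magnitude capped at 25 m so no dwell sample can leave the stay-point
radius. All timestamps share one fixed per-cohort UTC offset, keeping the
night window well defined.

Two geometric choices matter and were made once, deliberately. Places sit
at least three link radii apart (so distinct places can never merge), but
the default spacing is 4 km: over shorter hops at walking speed, the
first and last ~10 minutes of a movement remain within 150 m of the
flanking places and are absorbed into their stay points, which would
strip a 35-minute trip of its trajectory status. At 4 km the absorption
is ~2 minutes per end, and movements of 42–55 minutes therefore always
survive as trajectories — making the planted movement count exactly
recoverable, which the test suite asserts with zero tolerance. Second,
movements are scheduled between 07:00 and 22:00 with at least 45 minutes
of dwell between them, capped at 11 per day; participants are home at
night, so home inference has ground truth.

The generator does **not** emulate realistic human mobility (no routine
structure, no Lévy-flight trip lengths, no within-day missingness or
battery artifacts), and its app sessions are uniform in time rather than
circadian. Passing tests therefore demonstrate that the *pipeline*
recovers what was planted under clean conditions — they say nothing about
effect sizes or noise structure in real clinical streams, where the
discriminative signal is far weaker.

## Numerical and degenerate-input choices

* Ties in grid tuning go to the first grid row; place and fold ids are
  deterministic given seeds; Boruta is seeded per iteration.
* Participants with an empty stream get missing feature rows, which the
  train-mean imputer then fills inside each split.
* `pct_time_at_home` is 0 when no home can be inferred;
  `pct_places_visited_once` is missing when there are no places at all.
* Zero-length app sessions count for frequency and contribute nothing to
  duration; addiction windows shorter than one interval are errors, and
  any remainder shorter than one interval is ignored.
* A single-feature elastic net is fit with a penalty-neutral zero padding
  column (the solver requires two columns); the padding receives a zero
  coefficient and does not affect predictions.

## Problem sizes used by the validation suite

The synthetic studies in the test suite use cohorts of n = 220 (planted
effect, rates 2 vs 4, ten seeds) and n = 60 (null control, equal rates,
ten seeds) under the default generator conditions; Boruta recovery uses
one fixed n = 200 design with the informative feature among nine noise
columns, re-running the stochastic selector over ten seeds (a fresh noise
matrix contains, in expectation, about one column whose chance in-sample
correlation with the outcome gives it a persistent edge over its shadows
— such columns are genuinely in-sample informative, land tentative, and
are what the one-escape margin in the check absorbs); oracle equivalences
run on 500 fuzzed days (stay points) and 1,000 fuzzed score vectors
(AUROC). These sizes were chosen as the smallest at which the planted
effects are unambiguous.

## Known limitations

* The stay-point scan is order-dependent by construction (as is greedy
  place linkage); both match the standard algorithms but are not unique
  decompositions of a trace.
* The addiction score's denominator convention (full day) is one of
  several defensible readings of its definition; the explicit-window form
  is provided for the others.
* Boruta here tests hit counts after a fixed number of iterations rather
  than the original's sequential early stopping; with 100 iterations the
  two agree in practice but the p-values are not sequentially corrected.
* Class metrics use a fixed 0.5 threshold; no calibration is attempted.
* Exact Shapley enumeration is exponential in features and intentionally
  capped at 15.
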