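# digiphen

Digital phenotyping of smartphone mobility and app use for recognizing
depression/anxiety symptom status.

## What this package is for

Clinically relevant depression and anxiety frequently go unrecognized.
Passively logged smartphone data — GPS location and foreground app usage —
captures behavioral correlates of these conditions (reduced movement
between places, longer home stay, altered phone-use rhythms) without
burdening the participant. `digiphen` implements the full analysis a
digital-phenotyping study of this kind needs, for researchers who want a
tested, reproducible reference implementation:

* **Location markers.** Stay-point detection (a dwell within 150 m lasting
  ≥ 30 min, found by the classic sequential scan), greedy centroid linkage
  of repeat visits into unique places, home inference (most-visited of the
  top-3 nighttime places, night = 00:00–05:00), and trajectory extraction
  (runs between stay points with ≥ 20 samples over ≥ 30 min). Distances
  are haversine on a 6,371 km sphere.
* **App-use markers.** Per-category opening frequency and duration
  (sum/mean per day, overall and at night), total phone use, distinct app
  count, and an "addiction" score: the fraction of consecutive 20-minute
  intervals containing any app session.
* **Cohort assembly.** The symptomatic/asymptomatic labeling rule (any
  depressive or anxiety diagnosis, or IDS > 13, or BAI > 9), and the
  inclusion filter (≥ 7 observed days of *each* stream; iOS excluded).
* **The classification experiment.** Stratified 5-fold nested
  cross-validation with train-only min–max scaling and mean imputation,
  Boruta all-relevant feature selection (shadow features + random
  forests + binomial tests), grid-search-tuned elastic-net logistic
  regression and random forests maximizing AUROC, and evaluation against
  a dummy baseline with median/range aggregation of AUROC, accuracy and
  per-class precision/recall/F1.
* **Model explanation.** Exact Shapley values by coalition enumeration
  (marginal expectation over a training-fold background), with beeswarm
  export and value–attribution direction signs.
* **A synthetic cohort generator** that emulates the raw streams —
  10-minute stationary / 60-second moving sampling cadence, 4–43 days of
  coverage with whole-day missingness, group-conditional clinical scores —
  with a *plantable* difference in daily movement rate between symptomatic
  and asymptomatic participants, so the whole pipeline is testable against
  ground truth.

The AUROC is the probability that a random symptomatic participant scores
above a random asymptomatic one (ties at half credit): computed from rank
sums as `(Σ ranks₁ − n₁(n₁+1)/2) / (n₀ n₁)`. A Shapley attribution for
feature *i* is `Σ_S |S|!(p−|S|−1)!/p! · [v(S∪{i}) − v(S)]` with `v(S)` the
mean prediction over the background with the features in `S` pinned to the
explained instance.

## Worked example

The feature definitions come with worked examples; this reproduces them.
A three-day itinerary (home, work, gym / home, work, café / home,
theater, park as well-separated coordinates, each visit a > 30-min dwell):

```r
library(digiphen)

it <- demo_itinerary(seed = 1)
sp <- cluster_places(detect_stay_points(it))
nrow(sp)                    # 9   stay points in total (3 per day)
length(unique(sp$place_id)) # 6   unique places (home and work revisited)
infer_home(sp)              # 0   the home place founds cluster 0

ev <- demo_app_log()        # WhatsApp 2x1 min + Instagram 10 min on day 1,
                            # WhatsApp 1 min on day 2
app_frequency(ev, "communication")       # 1.5  opens per day (3 over 2 days)
app_duration(ev, "communication", "sum") # 1.5  minutes per day ((2+1)/2)

s4 <- data.frame(open_ts  = c(10, 11, 12, 13) * 3600,
                 close_ts = c(10, 11, 12, 13) * 3600 + 60)
addiction_score(s4, 10 * 3600, 14 * 3600)  # 0.333: 4 of 12 20-min intervals
```

A full synthetic study, end to end:

```r
cfg <- sim_config(n_participants = 220,
                  daily_trajectory_rate_symptomatic = 2,
                  daily_trajectory_rate_asymptomatic = 4, seed = 42)
cohort <- generate_cohort(cfg)
analysis <- apply_inclusion(cohort)       # filter + features + labels
report <- run_experiment(analysis,
                         experiment_config(digital_mode = "boruta", seed = 42))
report                                     # median AUROC per cell, stability
```

With the planted 2-vs-4 movements/day contrast, the digital-phenotyping
logistic model's median test AUROC sits far above the dummy's 0.50, the
total trajectory count is Boruta-confirmed in essentially every split, and
its Shapley value–attribution correlation is negative (fewer trajectories →
higher predicted probability of being symptomatic). The methods vignette
(`vignettes/digital-phenotyping-pipeline.Rmd`) documents the models,
parameter choices, and what the synthetic validation does and does not
show.

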