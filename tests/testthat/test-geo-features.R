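test_that("a jittered 45-minute dwell is one stay point; a steady walk is none", {
  set.seed(1)
  dwell <- make_dwell(52.1, 5.1, hm(0, "10:00"), hm(0, "10:45"),
                      period = 300, jitter_m = 60)
  sp <- detect_stay_points(dwell)
  expect_identical(nrow(sp), 1L)
  expect_gte(sp$departure_ts - sp$arrival_ts, 30 * 60)
  d <- hav_m(sp$centroid_lat, sp$centroid_lon, dwell$lat, dwell$lon)
  expect_true(all(d <= 150))

  # 1 km in 25 min: every 150-m window lasts well under 30 min
  walk <- make_move(52.1, 5.1, offset_m(52.1, 5.1, 1000, 0)["lat"],
                    offset_m(52.1, 5.1, 1000, 0)["lon"],
                    hm(0, "10:00"), hm(0, "10:25"), period = 60)
  expect_identical(nrow(detect_stay_points(walk)), 0L)
})

test_that("detector rejects unsorted input and degenerate streams", {
  s <- make_dwell(52.1, 5.1, 0, 3600, period = 600)
  expect_error(detect_stay_points(s[rev(seq_len(nrow(s))), ]), "sorted")
  expect_identical(nrow(detect_stay_points(s[1, , drop = FALSE])), 0L)
  expect_identical(nrow(detect_stay_points(s[0, , drop = FALSE])), 0L)
})

test_that("sequential scan matches the exhaustive-window oracle on fuzzed days", {
  for (s in 1:60) {
    day <- random_day(s)
    got <- detect_stay_points(day)
    want <- oracle_stay_points(day)
    expect_equal(nrow(got), nrow(want), info = paste("seed", s))
    if (nrow(got)) {
      expect_equal(got$start_idx, want$start_idx, info = paste("seed", s))
      expect_equal(got$end_idx, want$end_idx, info = paste("seed", s))
      expect_equal(got$centroid_lat, want$centroid_lat, tolerance = 1e-12)
      expect_equal(got$centroid_lon, want$centroid_lon, tolerance = 1e-12)
    }
  }
})

test_that("place clustering merges repeat visits and keeps far places apart", {
  # three visits to coincident coordinates -> one place
  sp <- do.call(rbind, lapply(0:2, function(d) {
    s <- make_dwell(52.1, 5.1, hm(d, "10:00"), hm(d, "11:00"))
    detect_stay_points(s)
  }))
  expect_identical(unique(cluster_places(sp)$place_id), 0L)

  # places >= 3 link radii apart: recovered count equals ground truth
  set.seed(7)
  for (r in 1:30) {
    k <- sample(2:6, 1)
    sp_list <- lapply(seq_len(k), function(i) {
      co <- offset_m(52.1, 5.1, (i - 1) * 500, sample(0:2000, 1))
      visits <- sample(1:3, 1)
      do.call(rbind, lapply(seq_len(visits), function(v) {
        s <- make_dwell(co["lat"], co["lon"], hm(v, "10:00"), hm(v, "10:40"),
                        jitter_m = 40)
        detect_stay_points(s)
      }))
    })
    sp_all <- do.call(rbind, sp_list)
    truth_all <- rep(seq_len(k), vapply(sp_list, nrow, integer(1)))
    ord <- order(sp_all$arrival_ts)
    sp <- sp_all[ord, , drop = FALSE]
    truth <- truth_all[ord]
    got <- cluster_places(sp)$place_id
    expect_identical(length(unique(got)), k)
    # place ids are dense in order of first visit, so they must equal the
    # ground-truth labels re-indexed by first appearance
    expect_identical(got,
                     as.integer(factor(truth, levels = unique(truth))) - 1L)
  }
})

test_that("home is the most visited of the top-3 nighttime places", {
  # apartment a: one long night dwell; apartment b: four visits with night
  # time; night club: one evening-to-night visit
  a <- offset_m(52.1, 5.1, 0, 0)
  b <- offset_m(52.1, 5.1, 2000, 0)
  club <- offset_m(52.1, 5.1, 0, 2000)
  mk <- function(co, day, from, to)
    detect_stay_points(make_dwell(co["lat"], co["lon"], hm(day, from),
                                  hm(day, to)))
  sp <- rbind(mk(a, 0, "00:00", "16:00"),
              mk(b, 1, "00:00", "09:00"), mk(b, 2, "00:00", "12:00"),
              mk(b, 3, "00:00", "10:00"), mk(b, 4, "00:00", "11:00"),
              mk(club, 5, "00:00", "07:00"))
  sp <- cluster_places(sp)
  b_id <- sp$place_id[2]
  expect_identical(infer_home(sp), b_id)
})

test_that("home inference handles single places and day-only data", {
  sp <- cluster_places(detect_stay_points(
    make_dwell(52.1, 5.1, hm(0, "02:00"), hm(0, "03:30"))))
  expect_identical(infer_home(sp), 0L)

  sp_day <- cluster_places(detect_stay_points(
    make_dwell(52.1, 5.1, hm(0, "09:00"), hm(0, "17:00"))))
  expect_identical(infer_home(sp_day), NA_integer_)
})

test_that("trajectory rule: both the point count and the duration must pass", {
  A <- c(lat = 52.1, lon = 5.1)
  B <- offset_m(52.1, 5.1, 5000, 0)   # 5 km: leaves the radius in ~1 min
  mk_day <- function(travel_min, period = 60) {
    rbind(make_dwell(A["lat"], A["lon"], hm(0, "08:00"), hm(0, "10:00")),
          make_move(A["lat"], A["lon"], B["lat"], B["lon"],
                    hm(0, "10:00") + period, hm(0, "10:00") + travel_min * 60,
                    period = period),
          make_dwell(B["lat"], B["lon"], hm(0, "10:00") + travel_min * 60 + 600,
                     hm(0, "10:00") + travel_min * 60 + 600 + 3 * 3600))
  }
  d35 <- mk_day(35)
  sp35 <- detect_stay_points(d35)
  expect_identical(nrow(sp35), 2L)
  expect_identical(nrow(extract_trajectories(d35, sp35)), 1L)

  d25 <- mk_day(25)
  expect_identical(nrow(extract_trajectories(d25, detect_stay_points(d25))), 0L)

  # 35 minutes but sampled every 10 min: duration passes, point count fails
  d4 <- mk_day(35, period = 600)
  expect_identical(nrow(extract_trajectories(d4, detect_stay_points(d4))), 0L)
})

test_that("runs before the first and after the last stay point are candidates", {
  A <- c(lat = 52.1, lon = 5.1)
  B <- offset_m(52.1, 5.1, 5000, 0)
  day <- rbind(make_move(A["lat"], A["lon"], B["lat"], B["lon"],
                         hm(0, "08:00"), hm(0, "08:40"), period = 60),
               make_dwell(B["lat"], B["lon"], hm(0, "08:50"), hm(0, "12:00")))
  sp <- detect_stay_points(day)
  tr <- extract_trajectories(day, sp)
  expect_identical(nrow(tr), 1L)
  expect_lt(tr$end_ts, sp$arrival_ts[1])
})

test_that("trajectory extraction recovers the planted movement count exactly", {
  for (s in 1:3) {
    d <- generate_cohort(sim_config(n_participants = 8, seed = 300 + s,
                                    days_range = c(5, 8), frac_ios = 0))
    geo <- geo_feature_table(d)
    m <- merge(geo, d$participants[, c("participant_id", "planted_n_movements")])
    expect_identical(as.integer(m$n_trajectories_total),
                     as.integer(m$planted_n_movements),
                     info = paste("seed", 300 + s))
  }
})

test_that("per-day averages use observed days: the three-day itinerary", {
  it <- demo_itinerary(seed = 2)
  ds <- structure(list(location_samples = it,
                       app_events = data.frame(participant_id = character(0),
                                               app_id = character(0),
                                               category = character(0),
                                               open_ts = numeric(0),
                                               close_ts = numeric(0)),
                       participants = data.frame(participant_id = "demo")),
                  class = "raw_dataset")
  g <- geo_feature_table(ds)
  expect_identical(as.integer(g$n_staypoints_total), 9L)
  expect_equal(g$n_staypoints_per_day, 3)
  expect_identical(as.integer(g$n_unique_staypoints_total), 6L)
  expect_equal(g$n_unique_staypoints_per_day, 2)
  expect_equal(g$pct_places_visited_once, 100 * 4 / 6)
  expect_identical(as.integer(g$n_trajectories_total), 0L)
})

test_that("average daily stationary time reproduces the two-day worked example", {
  # day 1 dwells 10, 8, 1 h; day 2 dwells 13, 9, 2 h -> 21.5 h per day
  places <- list(offset_m(52.1, 5.1, 0, 0), offset_m(52.1, 5.1, 2000, 0),
                 offset_m(52.1, 5.1, 0, 2000))
  mk <- function(day, from, hours, place)
    make_dwell(place["lat"], place["lon"], hm(day, from),
               hm(day, from) + hours * 3600)
  # 10 + 8 + 1 + 13 + 9 + 2 = 43 h of dwell across two observed days; the
  # 13-h dwell starts late on day 1 and runs into day 2 so both calendar
  # days hold samples but no third day is touched
  samples <- rbind(mk(0, "00:00", 10, places[[1]]),
                   mk(0, "10:10", 8, places[[2]]),
                   mk(0, "18:20", 1, places[[3]]),
                   mk(0, "19:30", 13, places[[1]]),   # ends 08:30 on day 2
                   mk(1, "08:40", 9, places[[2]]),
                   mk(1, "17:50", 2, places[[3]]))
  sp <- detect_stay_points(samples)
  expect_identical(nrow(sp), 6L)
  expect_equal(sum(sp$departure_ts - sp$arrival_ts) / 3600, 43, tolerance = 0.01)
  ds <- structure(list(location_samples = cbind(participant_id = "p", samples),
                       app_events = data.frame(participant_id = character(0),
                                               app_id = character(0),
                                               category = character(0),
                                               open_ts = numeric(0),
                                               close_ts = numeric(0)),
                       participants = data.frame(participant_id = "p")),
                  class = "raw_dataset")
  g <- geo_feature_table(ds)
  expect_equal(g$time_stationary_total_min / 60 / 2, 21.5, tolerance = 0.01)
})

test_that("a stationary participant is 100% at home with no trajectories", {
  samples <- do.call(rbind, lapply(0:9, function(d)
    make_dwell(52.1, 5.1, hm(d, "00:00"), hm(d, "23:50"))))
  ds <- structure(list(location_samples = cbind(participant_id = "p", samples),
                       app_events = data.frame(participant_id = character(0),
                                               app_id = character(0),
                                               category = character(0),
                                               open_ts = numeric(0),
                                               close_ts = numeric(0)),
                       participants = data.frame(participant_id = "p")),
                  class = "raw_dataset")
  g <- geo_feature_table(ds)
  expect_equal(g$pct_time_at_home, 100)
  expect_identical(as.integer(g$n_trajectories_total), 0L)
  expect_identical(as.integer(g$n_unique_staypoints_total), 1L)
})

test_that("participants without location data get missing feature rows", {
  ds <- structure(list(location_samples = data.frame(participant_id = character(0),
                                                     ts = numeric(0),
                                                     lat = numeric(0),
                                                     lon = numeric(0)),
                       app_events = data.frame(participant_id = character(0),
                                               app_id = character(0),
                                               category = character(0),
                                               open_ts = numeric(0),
                                               close_ts = numeric(0)),
                       participants = data.frame(participant_id = "p")),
                  class = "raw_dataset")
  g <- geo_feature_table(ds)
  expect_true(all(is.na(g[, -1])))
})

test_that("time is conserved and features are invariant to whole-day shifts", {
  d <- generate_cohort(sim_config(n_participants = 6, seed = 77,
                                  days_range = c(5, 7), frac_ios = 0))
  g1 <- geo_feature_table(d)
  span_ok <- vapply(d$participants$participant_id, function(p) {
    s <- d$location_samples[d$location_samples$participant_id == p, ]
    r <- g1[g1$participant_id == p, ]
    r$time_stationary_total_min + r$time_traveled_total_min <=
      (max(s$ts) - min(s$ts)) / 60 + 1e-9
  }, logical(1))
  expect_true(all(span_ok))

  d2 <- d
  d2$location_samples$ts <- d2$location_samples$ts + 5 * 86400
  g2 <- geo_feature_table(d2)
  expect_equal(g1, g2)
})
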