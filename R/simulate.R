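DIAGNOSIS_CODES <- c("MDD", "dysthymia", "social_phobia", "panic_disorder",
                     "GAD", "agoraphobia")

M_PER_DEG_LAT <- pi / 180 * 6371000  # 111194.93 m per degree latitude

# sample() that never treats a length-1 vector as 1:x
resample <- function(x, ...) x[sample.int(length(x), ...)]

# truncated normal via inverse-CDF; exact and loop-free
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

m_to_deg <- function(dx_m, dy_m, ref_lat) {
  cbind(dlat = dy_m / M_PER_DEG_LAT,
        dlon = dx_m / (M_PER_DEG_LAT * cos(ref_lat * pi / 180)))
}

# positional jitter (meters) with magnitude capped at 25 m so dwell samples
# can never leave the 150-m stay-point radius
sample_jitter <- function(n, sd_m) {
  dx <- rnorm(n, 0, sd_m)
  dy <- rnorm(n, 0, sd_m)
  r <- sqrt(dx^2 + dy^2)
  f <- ifelse(r > 25, 25 / r, 1)
  cbind(dx * f, dy * f)
}

#' Simulate one participant-day of location samples and app events
#'
#' Builds a day as alternating dwells and movements: the participant starts
#' the day at home (place 1), makes a Poisson-distributed number of
#' movements to other places between 07:00 and 22:00 local time, and dwells
#' at the destination in between. Dwells are sampled at the stationary
#' cadence with jittered positions; movements are sampled at the (denser)
#' moving cadence along the interpolated straight-line path. App sessions
#' open at distinct uniformly drawn times over the whole day with
#' log-normal durations. Consumes the current RNG stream.
#'
#' @param places matrix with columns `lat`, `lon`; row 1 is home.
#' @param rate expected number of movements (Poisson mean; realized count
#'   is capped at 11 by the daily schedule).
#' @param config a [sim_config()].
#' @param day local day index the samples belong to.
#' @param participant_id id string stamped on the output rows.
#' @param with_apps if `FALSE`, skip app events (stream-level missing day).
#' @param with_location if `FALSE`, skip location samples.
#' @return list with `samples` (ts, lat, lon), `app_events` (app_id,
#'   category, open_ts, close_ts) and `n_movements`, the realized planted
#'   movement count.
#' @export
simulate_participant_day <- function(places, rate, config, day,
                                     participant_id = "P000",
                                     with_apps = TRUE, with_location = TRUE) {
  stopifnot(nrow(places) >= 1)
  day0 <- day * SECONDS_PER_DAY          # local midnight, seconds
  tz <- config$tz_offset
  n_movements <- 0L
  samples <- data.frame(ts = numeric(0), lat = numeric(0), lon = numeric(0))

  if (with_location) {
    k <- min(rpois(1, rate), 11L)
    if (nrow(places) < 2) k <- 0L
    dur_rng <- config$movement_duration_range_min * 60
    starts <- durs <- numeric(0)
    if (k > 0) {
      prop <- sort(runif(k, 7 * 3600, 22 * 3600 - dur_rng[2]))
      d <- runif(k, dur_rng[1], dur_rng[2])
      prev_end <- -Inf
      for (j in seq_len(k)) {
        s <- max(prop[j], prev_end + 45 * 60)   # >= 45-min dwell in between
        if (s + d[j] > 22 * 3600) next
        starts <- c(starts, s)
        durs <- c(durs, d[j])
        prev_end <- s + d[j]
      }
    }
    n_movements <- length(starts)

    # place sequence: home, then a different place after every movement
    seq_places <- 1L
    for (j in seq_len(n_movements)) {
      cur <- seq_places[length(seq_places)]
      seq_places <- c(seq_places,
                      resample(setdiff(seq_len(nrow(places)), cur), 1))
    }

    ts <- lat <- lon <- list()
    dwell_start <- 0
    for (j in seq_len(n_movements + 1)) {
      p <- seq_places[j]
      dwell_end <- if (j <= n_movements) starts[j] - config$sampling_period_moving
                   else SECONDS_PER_DAY - 1
      tt <- seq(dwell_start, dwell_end, by = config$sampling_period_stationary)
      ts[[length(ts) + 1]] <- tt
      lat[[length(lat) + 1]] <- rep(places[p, "lat"], length(tt))
      lon[[length(lon) + 1]] <- rep(places[p, "lon"], length(tt))
      if (j <= n_movements) {
        q <- seq_places[j + 1]
        mt <- seq(starts[j], starts[j] + durs[j], by = config$sampling_period_moving)
        f <- (mt - starts[j]) / durs[j]
        ts[[length(ts) + 1]] <- mt
        lat[[length(lat) + 1]] <- places[p, "lat"] + f * (places[q, "lat"] - places[p, "lat"])
        lon[[length(lon) + 1]] <- places[p, "lon"] + f * (places[q, "lon"] - places[p, "lon"])
        dwell_start <- starts[j] + durs[j] + config$sampling_period_stationary
      }
    }
    ts <- unlist(ts); lat <- unlist(lat); lon <- unlist(lon)
    jit <- sample_jitter(length(ts), config$dwell_jitter_sd_m)
    dd <- m_to_deg(jit[, 1], jit[, 2], config$base_lat)
    samples <- data.frame(ts = day0 + ts - tz,
                          lat = lat + dd[, "dlat"],
                          lon = lon + dd[, "dlon"])
  }

  app_events <- data.frame(app_id = character(0), category = character(0),
                           open_ts = numeric(0), close_ts = numeric(0))
  if (with_apps) {
    m <- rpois(1, config$app_session_rate)
    if (m > 0) {
      opens <- sort(sample.int(SECONDS_PER_DAY, m)) - 1
      durs_s <- round(pmin(rlnorm(m, config$session_duration_meanlog,
                                  config$session_duration_sdlog), 10800))
      w <- config$app_category_weights
      cat_s <- sample(names(w), m, replace = TRUE, prob = w)
      app_id <- paste0(cat_s, "_app_", sample.int(5, m, replace = TRUE))
      app_events <- data.frame(app_id = app_id, category = cat_s,
                               open_ts = day0 + opens - tz,
                               close_ts = day0 + opens + durs_s - tz)
    }
  }

  if (nrow(samples)) samples <- cbind(participant_id = participant_id, samples)
  else samples <- data.frame(participant_id = character(0), ts = numeric(0),
                             lat = numeric(0), lon = numeric(0))
  if (nrow(app_events)) app_events <- cbind(participant_id = participant_id, app_events)
  else app_events <- data.frame(participant_id = character(0), app_id = character(0),
                                category = character(0), open_ts = numeric(0),
                                close_ts = numeric(0))
  list(samples = samples, app_events = app_events, n_movements = n_movements)
}

draw_scores <- function(symptomatic, diagnosed) {
  if (!symptomatic) {
    # asymptomatic: truncated below the symptomatic thresholds
    c(ids = round(rtnorm(1, 6.22, 3.59, 0, 13.49)),
      bai = round(rtnorm(1, 2.84, 2.50, 0, 9.49)))
  } else if (diagnosed) {
    c(ids = round(rtnorm(1, 21.63, 8.40, 0, Inf)),
      bai = round(rtnorm(1, 11.00, 6.35, 0, Inf)))
  } else {
    for (i in 1:50) {
      ids <- round(rtnorm(1, 21.63, 8.40, 0, Inf))
      bai <- round(rtnorm(1, 11.00, 6.35, 0, Inf))
      if (ids > 13 || bai > 9) return(c(ids = ids, bai = bai))
    }
    c(ids = 14, bai = 0)
  }
}

#' Generate a full synthetic cohort of raw digital-phenotyping streams
#'
#' Deterministic given `config$seed`. Each participant receives a planted
#' group (symptomatic / asymptomatic) with the corresponding expected daily
#' movement rate, a set of well-separated places, demographics, clinical
#' scores drawn so that the symptomatic labeling rule (any diagnosis, or
#' IDS > 13, or BAI > 9) holds exactly for the planted group, and 4-43 days
#' of location samples and app events with whole-day missingness.
#'
#' @param config a [sim_config()].
#' @return object of class `raw_dataset`: list with `location_samples`,
#'   `app_events` and `participants` data frames. The participants table
#'   carries the synthetic ground truth (`group`, `planted_n_movements`,
#'   `n_places`) alongside the observable fields (age, sex,
#'   years_education, ids, bai, diagnoses, os).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  n_sym <- round(n * config$frac_symptomatic)
  group <- sample(c(rep(1L, n_sym), rep(0L, n - n_sym)))
  dp <- config$demographics_params

  age <- round(rtnorm(n, dp$age_mean, dp$age_sd, 18, 80))
  edu <- round(rtnorm(n, dp$edu_mean, dp$edu_sd, 4, 25))
  sex <- ifelse(runif(n) < dp$p_female, "female", "male")
  os <- ifelse(runif(n) < config$frac_ios, "ios", "android")
  diagnosed <- group == 1L & runif(n) < config$p_diagnosis_symptomatic
  n_days <- resample(seq(config$days_range[1], config$days_range[2]), n,
                     replace = TRUE)

  ids_score <- bai_score <- integer(n)
  diagnoses <- character(n)
  for (i in seq_len(n)) {
    sc <- draw_scores(group[i] == 1L, diagnosed[i])
    ids_score[i] <- sc[["ids"]]
    bai_score[i] <- sc[["bai"]]
    diagnoses[i] <- if (diagnosed[i])
      paste(sample(DIAGNOSIS_CODES, sample(1:2, 1)), collapse = ";") else ""
  }

  loc_list <- app_list <- vector("list", n)
  planted_mov <- integer(n)
  n_places_v <- integer(n)
  for (i in seq_len(n)) {
    np <- resample(seq(config$n_places_range[1], config$n_places_range[2]), 1)
    n_places_v[i] <- np
    idx <- seq_len(np) - 1
    gx <- (idx %% 3) * config$place_spacing_m + runif(np, -50, 50)
    gy <- (idx %/% 3) * config$place_spacing_m + runif(np, -50, 50)
    dd <- m_to_deg(gx, gy, config$base_lat)
    places <- cbind(lat = config$base_lat + dd[, "dlat"],
                    lon = config$base_lon + dd[, "dlon"])
    rate <- if (group[i] == 1L) config$daily_trajectory_rate_symptomatic
            else config$daily_trajectory_rate_asymptomatic
    days <- config$origin_day + seq_len(n_days[i]) - 1
    loc_missing <- runif(n_days[i]) < config$missing_day_prob
    app_missing <- runif(n_days[i]) < config$missing_day_prob
    day_loc <- day_app <- vector("list", n_days[i])
    for (d in seq_len(n_days[i])) {
      sim <- simulate_participant_day(places, rate, config, days[d],
                                      participant_id = ids[i],
                                      with_apps = !app_missing[d],
                                      with_location = !loc_missing[d])
      day_loc[[d]] <- sim$samples
      day_app[[d]] <- sim$app_events
      planted_mov[i] <- planted_mov[i] + sim$n_movements
    }
    loc_list[[i]] <- do.call(rbind, day_loc)
    app_list[[i]] <- do.call(rbind, day_app)
  }

  participants <- data.frame(
    participant_id = ids, age = age, sex = sex, years_education = edu,
    ids = ids_score, bai = bai_score, diagnoses = diagnoses, os = os,
    group = group, planted_n_movements = planted_mov,
    n_places = n_places_v, stringsAsFactors = FALSE)

  out <- list(location_samples = do.call(rbind, loc_list),
              app_events = do.call(rbind, app_list),
              participants = participants)
  rownames(out$location_samples) <- NULL
  rownames(out$app_events) <- NULL
  class(out) <- "raw_dataset"
  out
}

#' @export
print.raw_dataset <- function(x, ...) {
  cat("<raw_dataset>\n")
  cat(sprintf("  %d participants, %d location samples, %d app events\n",
              nrow(x$participants), nrow(x$location_samples),
              nrow(x$app_events)))
  invisible(x)
}
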