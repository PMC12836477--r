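#' Detect stay points in a time-ordered location stream
#'
#' A stay point is an episode in which the participant remains within
#' `dist_threshold_m` of an anchor sample for at least `time_threshold_min`
#' minutes. The classic sequential scan is used: anchor the window at
#' sample i, advance j while sample j stays within the distance threshold
#' of the anchor, and when the window spans the minimum duration emit its
#' centroid and restart after it; otherwise slide the anchor forward by
#' one. The duration bound is inclusive (a dwell of exactly 30 minutes
#' counts), matching the inclusive phrasing of the trajectory rule.
#'
#' @param samples data frame with columns `ts` (UTC seconds, sorted
#'   ascending), `lat`, `lon`; one participant.
#' @param dist_threshold_m stay-point radius in meters (default 150).
#' @param time_threshold_min minimum dwell duration in minutes (default 30).
#' @return data frame with one row per stay point: `centroid_lat`,
#'   `centroid_lon`, `arrival_ts`, `departure_ts`, `start_idx`, `end_idx`
#'   (1-based indices of the member samples), in temporal order.
#' @export
detect_stay_points <- function(samples, dist_threshold_m = 150,
                               time_threshold_min = 30) {
  empty <- data.frame(centroid_lat = numeric(0), centroid_lon = numeric(0),
                      arrival_ts = numeric(0), departure_ts = numeric(0),
                      start_idx = integer(0), end_idx = integer(0))
  if (nrow(samples) < 2) return(empty)
  if (is.unsorted(samples$ts))
    stop("location samples must be sorted by timestamp", call. = FALSE)
  .scan_stay_points(as.numeric(samples$ts), as.numeric(samples$lat),
                    as.numeric(samples$lon), dist_threshold_m,
                    time_threshold_min * 60)
}

#' Cluster stay points of one participant into unique places
#'
#' Greedy sequential centroid linkage: each stay point, in temporal order,
#' joins the first existing place whose running centroid (mean of member
#' stay-point centroids) lies within `link_radius_m`; otherwise it founds a
#' new place. Repeated visits to the same physical location therefore share
#' a `place_id`. Deterministic given input order.
#'
#' @param stay_points output of [detect_stay_points()] for one participant.
#' @param link_radius_m linkage radius in meters (default 150).
#' @return `stay_points` with an integer `place_id` column, dense from 0 in
#'   order of first visit.
#' @export
cluster_places <- function(stay_points, link_radius_m = 150) {
  n <- nrow(stay_points)
  pid <- integer(n)
  c_lat <- c_lon <- c_n <- numeric(0)
  for (r in seq_len(n)) {
    hit <- NA_integer_
    if (length(c_lat)) {
      d <- haversine_m(stay_points$centroid_lat[r], stay_points$centroid_lon[r],
                       c_lat, c_lon)
      w <- which(d <= link_radius_m)
      if (length(w)) hit <- w[1]
    }
    if (is.na(hit)) {
      c_lat <- c(c_lat, stay_points$centroid_lat[r])
      c_lon <- c(c_lon, stay_points$centroid_lon[r])
      c_n <- c(c_n, 1)
      pid[r] <- length(c_lat) - 1L
    } else {
      c_lat[hit] <- (c_lat[hit] * c_n[hit] + stay_points$centroid_lat[r]) / (c_n[hit] + 1)
      c_lon[hit] <- (c_lon[hit] * c_n[hit] + stay_points$centroid_lon[r]) / (c_n[hit] + 1)
      c_n[hit] <- c_n[hit] + 1
      pid[r] <- hit - 1L
    }
  }
  stay_points$place_id <- pid
  stay_points
}

#' Infer the home place from nighttime dwell
#'
#' Ranks places by total dwell time intersected with the nightly
#' 00:00-05:00 local window; among the top three such places, home is the
#' one visited most often (most stay points), with ties broken by greater
#' night dwell and then by earlier `place_id`. Returns `NA` when no dwell
#' touches the night window.
#'
#' @param stay_points stay points with `place_id` (see [cluster_places()]).
#' @param tz_offset local-time offset in seconds.
#' @param night_start,night_end night window bounds, seconds past local
#'   midnight (defaults 00:00 and 05:00).
#' @return a single `place_id`, or `NA_integer_`.
#' @export
infer_home <- function(stay_points, tz_offset = 0,
                       night_start = NIGHT_START_S, night_end = NIGHT_END_S) {
  if (!nrow(stay_points)) return(NA_integer_)
  stopifnot("place_id" %in% names(stay_points))
  night_s <- night_overlap_seconds(stay_points$arrival_ts,
                                   stay_points$departure_ts, tz_offset,
                                   night_start, night_end)
  agg <- aggregate(cbind(night_s = night_s, visits = 1),
                   by = list(place_id = stay_points$place_id), FUN = sum)
  agg <- agg[agg$night_s > 0, , drop = FALSE]
  if (!nrow(agg)) return(NA_integer_)
  agg <- agg[order(-agg$night_s, agg$place_id), , drop = FALSE]
  top <- head(agg, 3)
  top <- top[order(-top$visits, -top$night_s, top$place_id), , drop = FALSE]
  as.integer(top$place_id[1])
}

#' Extract trajectories between stay points
#'
#' Candidate segments are the maximal runs of samples strictly between
#' consecutive stay-point member windows, plus the runs before the first
#' and after the last stay point (the whole stream when there are no stay
#' points). A candidate becomes a trajectory iff it contains at least
#' `min_points` samples and spans at least `min_duration_min` minutes.
#'
#' @param samples the same time-ordered samples the stay points were
#'   detected from.
#' @param stay_points output of [detect_stay_points()] on `samples`.
#' @param min_points minimum number of samples (default 20).
#' @param min_duration_min minimum span in minutes (default 30).
#' @return data frame with `start_ts`, `end_ts`, `n_points`,
#'   `path_length_m` (sum of consecutive haversine distances).
#' @export
extract_trajectories <- function(samples, stay_points, min_points = 20,
                                 min_duration_min = 30) {
  n <- nrow(samples)
  bounds <- rbind(c(0L, if (nrow(stay_points)) stay_points$start_idx[1] else n + 1L))
  if (nrow(stay_points)) {
    k <- nrow(stay_points)
    if (k > 1)
      bounds <- rbind(bounds, cbind(stay_points$end_idx[-k], stay_points$start_idx[-1]))
    bounds <- rbind(bounds, c(stay_points$end_idx[k], n + 1L))
  }
  out <- list()
  for (r in seq_len(nrow(bounds))) {
    lo <- bounds[r, 1] + 1L
    hi <- bounds[r, 2] - 1L
    if (hi < lo) next
    npts <- hi - lo + 1L
    dur <- samples$ts[hi] - samples$ts[lo]
    if (npts >= min_points && dur >= min_duration_min * 60) {
      path <- if (npts > 1)
        sum(haversine_m(samples$lat[lo:(hi - 1)], samples$lon[lo:(hi - 1)],
                        samples$lat[(lo + 1):hi], samples$lon[(lo + 1):hi]))
      else 0
      out[[length(out) + 1]] <- data.frame(start_ts = samples$ts[lo],
                                           end_ts = samples$ts[hi],
                                           n_points = npts,
                                           path_length_m = path)
    }
  }
  if (!length(out))
    return(data.frame(start_ts = numeric(0), end_ts = numeric(0),
                      n_points = integer(0), path_length_m = numeric(0)))
  do.call(rbind, out)
}

geo_feature_names <- function() {
  c("n_staypoints_total", "n_staypoints_per_day", "n_unique_staypoints_total",
    "n_unique_staypoints_per_day", "time_stationary_total_min",
    "time_stationary_mean_min", "pct_time_at_home", "n_trajectories_total",
    "time_traveled_total_min", "pct_places_visited_once")
}

#' Per-participant location feature table
#'
#' Runs stay-point detection, place clustering, home inference and
#' trajectory extraction for every participant and summarizes them into
#' one row per participant. Per-day averages divide totals by the number
#' of local calendar days with at least one location sample. Participants
#' with no location samples receive a row of missing values (mean-imputed
#' downstream).
#'
#' @param dataset a `raw_dataset`.
#' @param dist_threshold_m,time_threshold_min stay-point thresholds.
#' @param min_traj_points,min_traj_duration_min trajectory thresholds.
#' @param tz_offset local-time offset in seconds.
#' @return data frame keyed by `participant_id` with columns
#'   `n_staypoints_total`, `n_staypoints_per_day`,
#'   `n_unique_staypoints_total`, `n_unique_staypoints_per_day`,
#'   `time_stationary_total_min`, `time_stationary_mean_min`,
#'   `pct_time_at_home` (0 when no home can be inferred),
#'   `n_trajectories_total`, `time_traveled_total_min`,
#'   `pct_places_visited_once`.
#' @export
geo_feature_table <- function(dataset, dist_threshold_m = 150,
                              time_threshold_min = 30, min_traj_points = 20,
                              min_traj_duration_min = 30, tz_offset = 0) {
  pts <- dataset$participants$participant_id
  loc <- dataset$location_samples
  by_pt <- split(seq_len(nrow(loc)), loc$participant_id)
  rows <- lapply(pts, function(p) {
    idx <- by_pt[[p]]
    if (is.null(idx)) idx <- integer(0)
    s <- loc[idx, c("ts", "lat", "lon"), drop = FALSE]
    s <- s[order(s$ts), , drop = FALSE]
    row <- as.list(setNames(rep(NA_real_, length(geo_feature_names())),
                            geo_feature_names()))
    if (!nrow(s)) return(c(list(participant_id = p), row))
    n_days <- length(unique(day_index(s$ts, tz_offset)))
    sp <- detect_stay_points(s, dist_threshold_m, time_threshold_min)
    sp <- cluster_places(sp, dist_threshold_m)
    tr <- extract_trajectories(s, sp, min_traj_points, min_traj_duration_min)
    dwell_min <- (sp$departure_ts - sp$arrival_ts) / 60

    row$n_staypoints_total <- nrow(sp)
    row$n_staypoints_per_day <- nrow(sp) / n_days
    n_places <- length(unique(sp$place_id))
    row$n_unique_staypoints_total <- n_places
    row$n_unique_staypoints_per_day <- n_places / n_days
    row$time_stationary_total_min <- sum(dwell_min)
    row$time_stationary_mean_min <- if (nrow(sp)) mean(dwell_min) else NA_real_
    home <- infer_home(sp, tz_offset)
    row$pct_time_at_home <- if (is.na(home) || sum(dwell_min) == 0) 0 else
      100 * sum(dwell_min[sp$place_id == home]) / sum(dwell_min)
    row$n_trajectories_total <- nrow(tr)
    row$time_traveled_total_min <- sum((tr$end_ts - tr$start_ts) / 60)
    row$pct_places_visited_once <- if (n_places == 0) NA_real_ else
      100 * sum(table(sp$place_id) == 1) / n_places
    c(list(participant_id = p), row)
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
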