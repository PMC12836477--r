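#' @keywords internal
SECONDS_PER_DAY <- 86400

# Night window: 00:00-05:00 local, used for both app night features and
# home inference. Stored as seconds past local midnight.
NIGHT_START_S <- 0
NIGHT_END_S <- 5 * 3600

#' Local calendar day index of a UTC timestamp
#'
#' Timestamps are numeric UTC seconds; local time is UTC plus a fixed
#' per-cohort offset. The day index is the number of whole local days since
#' the epoch, so two timestamps share an index iff they fall on the same
#' local calendar day.
#'
#' @param ts_utc numeric vector of UTC seconds.
#' @param tz_offset fixed local-time offset in seconds (one value per cohort).
#' @return integer-valued numeric vector of day indices.
#' @export
day_index <- function(ts_utc, tz_offset = 0) {
  floor((ts_utc + tz_offset) / SECONDS_PER_DAY)
}

#' Seconds past local midnight
#' @inheritParams day_index
#' @return numeric vector in `[0, 86400)`.
#' @export
time_of_day <- function(ts_utc, tz_offset = 0) {
  (ts_utc + tz_offset) %% SECONDS_PER_DAY
}

#' Overlap of a time interval with the nightly 00:00-05:00 window
#'
#' Sums, over every local calendar day an interval touches, the overlap of
#' the interval with that day's night window.
#'
#' @param start_utc,end_utc interval bounds, UTC seconds (`end >= start`).
#' @inheritParams day_index
#' @param night_start,night_end night window bounds as seconds past local
#'   midnight.
#' @return numeric vector of overlap durations in seconds.
#' @export
night_overlap_seconds <- function(start_utc, end_utc, tz_offset = 0,
                                  night_start = NIGHT_START_S,
                                  night_end = NIGHT_END_S) {
  stopifnot(length(start_utc) == length(end_utc))
  vapply(seq_along(start_utc), function(i) {
    s <- start_utc[i] + tz_offset
    e <- end_utc[i] + tz_offset
    if (e <= s) return(0)
    days <- floor(s / SECONDS_PER_DAY):floor(e / SECONDS_PER_DAY)
    ws <- days * SECONDS_PER_DAY + night_start
    we <- days * SECONDS_PER_DAY + night_end
    sum(pmax(0, pmin(e, we) - pmax(s, ws)))
  }, numeric(1))
}

# Great-circle distance in meters on a sphere of radius 6,371,000 m;
# sub-meter accuracy at the 150-m scales the stay-point rule operates on.
haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

# Timestamp helper: seconds for day d (0-based) at "HH:MM[:SS]" local time.
ts_at <- function(day, hms, tz_offset = 0) {
  parts <- as.numeric(strsplit(hms, ":", fixed = TRUE)[[1]])
  if (length(parts) == 2) parts <- c(parts, 0)
  day * SECONDS_PER_DAY + parts[1] * 3600 + parts[2] * 60 + parts[3] - tz_offset
}
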