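#' Worked-example location itinerary
#'
#' A synthetic three-day itinerary over six well-separated places with
#' nine dwells - home, work and the gym on day 1; home, work and a cafe
#' on day 2; home, a theater and a park on day 3. Each dwell is sampled
#' every 10 minutes with positional jitter under 25 m and lasts well over
#' 30 minutes, so stay-point detection recovers exactly one stay point
#' per dwell and place clustering recovers the six places.
#'
#' @param seed integer seed for the positional jitter.
#' @param tz_offset local-time offset in seconds.
#' @return data frame of location samples (`participant_id`, `ts`,
#'   `lat`, `lon`) with attribute `"places"` naming the true place of
#'   each dwell.
#' @export
demo_itinerary <- function(seed = 1, tz_offset = 0) {
  base_lat <- 52.1; base_lon <- 5.1
  # places ~2 km apart on a grid
  off <- list(home = c(0, 0), work = c(2000, 0), gym = c(0, 2000),
              cafe = c(2000, 2000), theater = c(4000, 0), park = c(0, 4000))
  place_coord <- function(nm) {
    dd <- m_to_deg(off[[nm]][1], off[[nm]][2], base_lat)
    c(lat = base_lat + unname(dd[, "dlat"]),
      lon = base_lon + unname(dd[, "dlon"]))
  }
  dwells <- rbind(
    data.frame(day = 0, place = c("home", "work", "gym"),
               from = c("00:00", "09:00", "18:00"),
               to = c("08:00", "17:00", "19:00")),
    data.frame(day = 1, place = c("home", "work", "cafe"),
               from = c("00:00", "09:00", "18:00"),
               to = c("08:00", "17:00", "19:00")),
    data.frame(day = 2, place = c("home", "theater", "park"),
               from = c("00:00", "10:00", "13:00"),
               to = c("08:00", "12:00", "15:00")))
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(dwells)), function(i) {
      co <- place_coord(dwells$place[i])
      tt <- seq(ts_at(dwells$day[i], dwells$from[i], tz_offset),
                ts_at(dwells$day[i], dwells$to[i], tz_offset), by = 600)
      jit <- sample_jitter(length(tt), 8)
      dd <- m_to_deg(jit[, 1], jit[, 2], base_lat)
      data.frame(participant_id = "demo", ts = tt,
                 lat = co[["lat"]] + dd[, "dlat"],
                 lon = co[["lon"]] + dd[, "dlon"])
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$ts), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "places") <- dwells$place
    out
  })
}

#' Worked-example app-usage log
#'
#' Two days of foreground app events: three WhatsApp sessions (a
#' communication app) of one minute each and one ten-minute Instagram
#' session (a social app), as used throughout the app-feature
#' documentation.
#'
#' @param tz_offset local-time offset in seconds.
#' @return data frame of app events (`participant_id`, `app_id`,
#'   `category`, `open_ts`, `close_ts`).
#' @export
demo_app_log <- function(tz_offset = 0) {
  data.frame(
    participant_id = "demo",
    app_id = c("WhatsApp", "WhatsApp", "Instagram", "WhatsApp"),
    category = c("communication", "communication", "social", "communication"),
    open_ts = c(ts_at(0, "10:00", tz_offset), ts_at(0, "11:00", tz_offset),
                ts_at(0, "11:30", tz_offset), ts_at(1, "10:00", tz_offset)),
    close_ts = c(ts_at(0, "10:01", tz_offset), ts_at(0, "11:01", tz_offset),
                 ts_at(0, "11:40", tz_offset), ts_at(1, "10:01", tz_offset)),
    stringsAsFactors = FALSE)
}
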