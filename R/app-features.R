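#' Default app category vocabulary
#'
#' The configured categories app sessions are aggregated into. Apps with a
#' category outside this vocabulary are treated as `other` by the
#' synthetic generator; the feature functions reject unknown categories
#' outright.
#'
#' @return character vector of category names, sorted.
#' @export
app_categories <- function() {
  sort(c("communication", "social", "entertainment", "other"))
}

check_category <- function(category, categories) {
  if (!category %in% categories)
    stop(sprintf("unknown app category '%s'; configured categories: %s",
                 category, paste(categories, collapse = ", ")), call. = FALSE)
}

#' Split app sessions at local midnight
#'
#' Every per-day statistic operates on session pieces that do not cross a
#' local midnight, so no session is counted on two days and total duration
#' is conserved by the split. The piece containing the original open
#' timestamp is flagged `is_open`; frequency statistics count only those.
#' Night membership is decided per piece by its (piece) open timestamp
#' falling in 00:00-05:00 local, with the whole piece duration counted, so
#' a 04:55-05:20 session contributes all 25 minutes to the night total.
#'
#' @param events data frame with `open_ts`, `close_ts` (UTC seconds) and
#'   any other columns, which are carried through.
#' @param tz_offset local-time offset in seconds.
#' @return the events expanded into pieces, with added columns `day`
#'   (local day index of the piece), `is_open`, and `is_night`.
#' @export
split_sessions_at_midnight <- function(events, tz_offset = 0) {
  if (!nrow(events)) {
    out <- events
    out$day <- numeric(0); out$is_open <- logical(0); out$is_night <- logical(0)
    return(out)
  }
  d_open <- day_index(events$open_ts, tz_offset)
  d_close <- day_index(events$close_ts, tz_offset)
  crosses <- which(d_close > d_open)
  pieces <- list(events[setdiff(seq_len(nrow(events)), crosses), , drop = FALSE])
  pieces[[1]]$is_open <- rep(TRUE, nrow(pieces[[1]]))
  for (i in crosses) {
    days <- d_open[i]:d_close[i]
    starts <- pmax(events$open_ts[i], days * SECONDS_PER_DAY - tz_offset)
    ends <- pmin(events$close_ts[i], (days + 1) * SECONDS_PER_DAY - tz_offset)
    keep <- ends > starts | seq_along(days) == 1   # drop empty trailing piece
    pc <- events[rep(i, sum(keep)), , drop = FALSE]
    pc$open_ts <- starts[keep]
    pc$close_ts <- ends[keep]
    pc$is_open <- seq_len(nrow(pc)) == 1
    pieces[[length(pieces) + 1]] <- pc
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$open_ts), , drop = FALSE]
  rownames(out) <- NULL
  out$day <- day_index(out$open_ts, tz_offset)
  tod <- time_of_day(out$open_ts, tz_offset)
  out$is_night <- tod >= NIGHT_START_S & tod < NIGHT_END_S
  out
}

observed_app_days <- function(pieces) unique(pieces$day)

#' Per-day app opening frequency for a category
#'
#' Number of sessions of the category opened per day (night variant:
#' opened between 00:00 and 05:00 local), divided by the number of local
#' calendar days with at least one app event of any category.
#'
#' @param events one participant's app events (`app_id`, `category`,
#'   `open_ts`, `close_ts`).
#' @param category category to count.
#' @param night_only if `TRUE`, count only night openings.
#' @param tz_offset local-time offset in seconds.
#' @param categories configured category vocabulary.
#' @return average openings per observed day (0 if the category is absent).
#' @export
app_frequency <- function(events, category, night_only = FALSE,
                          tz_offset = 0, categories = app_categories()) {
  check_category(category, categories)
  pc <- split_sessions_at_midnight(events, tz_offset)
  days <- observed_app_days(pc)
  if (!length(days)) return(NA_real_)
  sel <- pc$is_open & pc$category == category
  if (night_only) sel <- sel & pc$is_night
  sum(sel) / length(days)
}

#' Per-day app usage duration for a category
#'
#' For `stat = "sum"`, sums the session durations of the category on each
#' observed day (days without a session of the category contribute 0) and
#' averages over all observed days. For `stat = "mean"`, takes the mean
#' session duration on each day that has at least one session of the
#' category and averages over those days only (0 when no day qualifies).
#'
#' @inheritParams app_frequency
#' @param stat `"sum"` or `"mean"`.
#' @return average minutes per day.
#' @export
app_duration <- function(events, category, stat = c("sum", "mean"),
                         night_only = FALSE, tz_offset = 0,
                         categories = app_categories()) {
  stat <- match.arg(stat)
  check_category(category, categories)
  pc <- split_sessions_at_midnight(events, tz_offset)
  days <- observed_app_days(pc)
  if (!length(days)) return(NA_real_)
  sel <- pc$category == category
  if (night_only) sel <- sel & pc$is_night
  pc <- pc[sel, , drop = FALSE]
  if (!nrow(pc)) return(0)
  dur_min <- (pc$close_ts - pc$open_ts) / 60
  per_day <- tapply(dur_min, pc$day, if (stat == "sum") sum else mean)
  if (stat == "sum") sum(per_day) / length(days) else mean(per_day)
}

#' App addiction score over an explicit observation window
#'
#' Partitions the window into consecutive intervals of `interval_min`
#' minutes (any remainder shorter than one interval is ignored) and
#' returns the fraction of intervals during which at least one app session
#' was in progress. 1 means apps were used in every interval.
#'
#' @param events one participant's app events.
#' @param window_start,window_end window bounds, UTC seconds.
#' @param interval_min interval length in minutes (default 20).
#' @return proportion in `[0, 1]`.
#' @export
addiction_score <- function(events, window_start, window_end,
                            interval_min = 20) {
  if (window_end <= window_start)
    stop("window_end must exceed window_start", call. = FALSE)
  L <- interval_min * 60
  n_int <- floor((window_end - window_start) / L)
  if (n_int < 1)
    stop("observation window is shorter than one interval", call. = FALSE)
  starts <- window_start + (seq_len(n_int) - 1) * L
  hit <- vapply(starts, function(a) {
    any(events$open_ts < a + L & events$close_ts >= a)
  }, logical(1))
  sum(hit) / n_int
}

#' Daily app addiction score averaged over observed days
#'
#' Applies [addiction_score()] to each observed local calendar day, using
#' the full day (72 intervals of 20 minutes) as the observation window,
#' and averages over days with at least one app event.
#'
#' @inheritParams app_frequency
#' @param interval_min interval length in minutes.
#' @return average daily proportion in `[0, 1]`, `NA` with no app days.
#' @export
daily_addiction_score <- function(events, tz_offset = 0, interval_min = 20) {
  pc <- split_sessions_at_midnight(events, tz_offset)
  daily_addiction_from_pieces(pc, tz_offset, interval_min)
}

# interval-index form of addiction_score() over whole-day windows; a
# session piece [o, c] covers the consecutive intervals containing o..c
daily_addiction_from_pieces <- function(pc, tz_offset, interval_min) {
  days <- sort(observed_app_days(pc))
  if (!length(days)) return(NA_real_)
  L <- interval_min * 60
  n_int <- floor(SECONDS_PER_DAY / L)
  by_day <- split(seq_len(nrow(pc)), pc$day)
  scores <- vapply(days, function(d) {
    idx <- by_day[[as.character(d)]]
    w0 <- d * SECONDS_PER_DAY - tz_offset
    i1 <- pmax(0, floor((pc$open_ts[idx] - w0) / L))
    i2 <- pmin(n_int - 1, floor((pc$close_ts[idx] - w0) / L))
    length(unique(unlist(Map(seq, i1, i2)))) / n_int
  }, numeric(1))
  mean(scores)
}

#' Per-participant app-usage feature table
#'
#' Assembles, for every configured category, per-day opening frequency and
#' duration statistics (overall and for the 00:00-05:00 night window),
#' plus the daily addiction score, the number of distinct apps used over
#' the whole observation, and total phone use in hours per observed day.
#' Participants with no app events receive a row of missing values.
#'
#' @param dataset a `raw_dataset`.
#' @param tz_offset local-time offset in seconds.
#' @param interval_min addiction-score interval in minutes.
#' @param categories configured category vocabulary (columns appear in
#'   sorted category order).
#' @return data frame keyed by `participant_id`.
#' @export
app_feature_table <- function(dataset, tz_offset = 0, interval_min = 20,
                              categories = app_categories()) {
  categories <- sort(categories)
  pts <- dataset$participants$participant_id
  ev <- dataset$app_events
  by_pt <- split(seq_len(nrow(ev)), ev$participant_id)
  per_cat_cols <- function(c) {
    paste0(c("freq_", "freq_night_", "dur_sum_", "dur_mean_",
             "dur_sum_night_", "dur_mean_night_"), c,
           c("_per_day", "_per_day", "_min_per_day", "_min_per_day",
             "_min_per_day", "_min_per_day"))
  }
  all_cols <- c(unlist(lapply(categories, per_cat_cols)),
                "addiction_score", "n_distinct_apps",
                "total_phone_use_hours_per_day")
  rows <- lapply(pts, function(p) {
    idx <- by_pt[[p]]
    if (is.null(idx)) idx <- integer(0)
    e <- ev[idx, , drop = FALSE]
    e <- e[order(e$open_ts), , drop = FALSE]
    row <- as.list(setNames(rep(NA_real_, length(all_cols)), all_cols))
    if (nrow(e)) {
      # split once; the per-category statistics below are the same
      # quantities app_frequency()/app_duration() compute piecemeal
      pc <- split_sessions_at_midnight(e, tz_offset)
      n_days <- length(observed_app_days(pc))
      dur_min <- (pc$close_ts - pc$open_ts) / 60
      for (cc in categories) {
        in_cat <- pc$category == cc
        row[[paste0("freq_", cc, "_per_day")]] <-
          sum(pc$is_open & in_cat) / n_days
        row[[paste0("freq_night_", cc, "_per_day")]] <-
          sum(pc$is_open & in_cat & pc$is_night) / n_days
        for (night in c(FALSE, TRUE)) {
          sel <- if (night) in_cat & pc$is_night else in_cat
          sfx <- if (night) "_night_" else "_"
          if (!any(sel)) {
            row[[paste0("dur_sum", sfx, cc, "_min_per_day")]] <- 0
            row[[paste0("dur_mean", sfx, cc, "_min_per_day")]] <- 0
          } else {
            per_day_sum <- tapply(dur_min[sel], pc$day[sel], sum)
            per_day_mean <- tapply(dur_min[sel], pc$day[sel], mean)
            row[[paste0("dur_sum", sfx, cc, "_min_per_day")]] <-
              sum(per_day_sum) / n_days
            row[[paste0("dur_mean", sfx, cc, "_min_per_day")]] <-
              mean(per_day_mean)
          }
        }
      }
      row$addiction_score <- daily_addiction_from_pieces(pc, tz_offset,
                                                         interval_min)
      row$n_distinct_apps <- length(unique(e$app_id))
      row$total_phone_use_hours_per_day <-
        sum(e$close_ts - e$open_ts) / 3600 / n_days
    }
    c(list(participant_id = p), row)
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
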