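#' Binary symptom label from clinical scores and diagnoses
#'
#' A participant is symptomatic (1) iff they carry at least one depressive
#' or anxiety disorder diagnosis, or their IDS score exceeds 13, or their
#' BAI score exceeds 9 (both strict inequalities); otherwise asymptomatic
#' (0). Pure function of its arguments; the two classes are exhaustive and
#' mutually exclusive.
#'
#' @param ids Inventory of Depressive Symptomatology total score (>= 0).
#' @param bai Beck Anxiety Inventory total score (>= 0).
#' @param diagnoses character vector of diagnosis codes (possibly empty),
#'   or a single semicolon-joined string as stored in the participants
#'   table ("" meaning none).
#' @param ids_threshold,bai_threshold strict thresholds (defaults 13, 9).
#' @return integer 0 or 1.
#' @export
label_participant <- function(ids, bai, diagnoses = character(0),
                              ids_threshold = 13, bai_threshold = 9) {
  if (is.na(ids) || is.na(bai) || ids < 0 || bai < 0)
    stop("IDS and BAI scores must be nonnegative", call. = FALSE)
  if (length(diagnoses) == 1 && is.character(diagnoses))
    diagnoses <- strsplit(diagnoses, ";", fixed = TRUE)[[1]]
  diagnoses <- diagnoses[nzchar(diagnoses)]
  as.integer(length(diagnoses) > 0 || ids > ids_threshold || bai > bai_threshold)
}

stream_day_counts <- function(dataset, tz_offset = 0) {
  pts <- dataset$participants$participant_id
  # app days are counted on midnight-split session pieces, matching the
  # denominators used by the app feature functions
  pieces <- split_sessions_at_midnight(dataset$app_events, tz_offset)
  loc_days <- tapply(day_index(dataset$location_samples$ts, tz_offset),
                     dataset$location_samples$participant_id,
                     function(d) length(unique(d)))
  app_days <- tapply(pieces$day, pieces$participant_id,
                     function(d) length(unique(d)))
  data.frame(participant_id = pts,
             location_days = ifelse(is.na(loc_days[pts]), 0L, loc_days[pts]),
             app_days = ifelse(is.na(app_days[pts]), 0L, app_days[pts]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the inclusion filter and assemble the analysis dataset
#'
#' Excludes participants with an iOS operating system (app logging is
#' unavailable there), participants without any digital phenotyping data,
#' and participants with fewer than `min_days` days of either stream (a
#' day counts when it has at least one sample of that stream); included
#' participants therefore have at least `min_days` days of each. For the
#' survivors it extracts location and app features, merges demographics
#' (sex encoded female = 1) and applies the symptom labeling rule.
#' Idempotent: re-applying the filter to the survivors changes nothing.
#'
#' @param dataset a `raw_dataset`.
#' @param min_days minimum days of each stream (default 7).
#' @param tz_offset local-time offset in seconds.
#' @param ... passed to [geo_feature_table()] / [app_feature_table()].
#' @return object of class `analysis_dataset`: list with `features` (one
#'   row per included participant: demographics + geo + app features),
#'   `labels` (named 0/1 integer vector), `exclusions` (participant_id,
#'   reason in no_data / ios / insufficient_days) and `day_counts`.
#' @export
apply_inclusion <- function(dataset, min_days = 7, tz_offset = 0, ...) {
  stopifnot(inherits(dataset, "raw_dataset"))
  pt <- dataset$participants
  dc <- stream_day_counts(dataset, tz_offset)
  reason <- rep(NA_character_, nrow(pt))
  reason[dc$location_days == 0 & dc$app_days == 0] <- "no_data"
  reason[is.na(reason) & pt$os == "ios"] <- "ios"
  reason[is.na(reason) &
           (dc$location_days < min_days | dc$app_days < min_days)] <- "insufficient_days"
  keep <- is.na(reason)
  if (!any(keep))
    stop("no participants survive the inclusion filter", call. = FALSE)

  survivors <- pt$participant_id[keep]
  sub <- list(location_samples =
                dataset$location_samples[dataset$location_samples$participant_id
                                         %in% survivors, , drop = FALSE],
              app_events =
                dataset$app_events[dataset$app_events$participant_id
                                   %in% survivors, , drop = FALSE],
              participants = pt[keep, , drop = FALSE])
  class(sub) <- "raw_dataset"

  geo <- geo_feature_table(sub, tz_offset = tz_offset, ...)
  app <- app_feature_table(sub, tz_offset = tz_offset)
  demo <- data.frame(participant_id = sub$participants$participant_id,
                     age = sub$participants$age,
                     sex = as.integer(sub$participants$sex == "female"),
                     years_education = sub$participants$years_education,
                     stringsAsFactors = FALSE)
  features <- merge(merge(demo, geo, by = "participant_id"), app,
                    by = "participant_id", sort = FALSE)
  features <- features[match(survivors, features$participant_id), , drop = FALSE]
  rownames(features) <- NULL

  labels <- vapply(seq_along(survivors), function(i) {
    r <- sub$participants[i, ]
    label_participant(r$ids, r$bai, r$diagnoses)
  }, integer(1))
  names(labels) <- survivors

  out <- list(features = features, labels = labels,
              exclusions = data.frame(participant_id = pt$participant_id[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE),
              day_counts = dc)
  class(out) <- "analysis_dataset"
  out
}

#' @export
print.analysis_dataset <- function(x, ...) {
  cat("<analysis_dataset>\n")
  cat(sprintf("  %d included participants (%d symptomatic / %d asymptomatic)\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0)))
  cat(sprintf("  %d features; %d excluded (%s)\n",
              ncol(x$features) - 1L, nrow(x$exclusions),
              if (nrow(x$exclusions))
                paste(names(table(x$exclusions$reason)),
                      table(x$exclusions$reason), sep = ":", collapse = ", ")
              else "none"))
  invisible(x)
}
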