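#' Simulation configuration for a synthetic digital-phenotyping cohort
#'
#' Bundles every knob of the raw-stream generator. Defaults describe a
#' moderate cohort in which symptomatic participants move between places
#' half as often as asymptomatic ones (2 vs 4 expected movements per day),
#' location is sampled every 10 minutes while stationary and every 60
#' seconds while moving, and per-participant coverage spans 4-43 days so
#' that the 7-day inclusion filter is exercised.
#'
#' @param n_participants number of participants to simulate.
#' @param frac_symptomatic proportion of participants in the symptomatic
#'   group, in `[0, 1]`.
#' @param days_range integer `c(min, max)` of per-participant coverage in
#'   days, within `[1, 43]`.
#' @param sampling_period_stationary seconds between location samples while
#'   dwelling at a place (default 600 s = the 10-minute baseline cadence).
#' @param sampling_period_moving seconds between location samples during
#'   movement (default 60 s, so a 30+ minute trip always yields the 20
#'   points a trajectory requires).
#' @param daily_trajectory_rate_symptomatic expected number of movements
#'   between places per day for symptomatic participants (Poisson mean).
#' @param daily_trajectory_rate_asymptomatic same, asymptomatic group.
#' @param n_places_range integer `c(min, max)` of distinct places per
#'   participant (place 1 is home).
#' @param place_spacing_m grid spacing between places in meters. Must be at
#'   least 550 m so that after +/-50 m jitter no two places come within
#'   three stay-point radii (450 m) of each other and distinct places can
#'   never merge during place clustering. The default 4 km additionally
#'   makes movements fast enough to leave the 150-m radius of the origin
#'   place within about 2 minutes, so the sample run strictly between two
#'   stay points retains the >= 20 points over >= 30 minutes a trajectory
#'   requires.
#' @param app_session_rate expected number of app sessions per day.
#' @param app_category_weights named numeric vector of per-category session
#'   probabilities; must sum to 1.
#' @param demographics_params list with `age_mean`, `age_sd`, `edu_mean`,
#'   `edu_sd`, `p_female`.
#' @param missing_day_prob probability that a whole calendar day yields no
#'   samples; applied independently per stream.
#' @param frac_ios fraction of participants assigned the iOS operating
#'   system (excluded downstream because app logging is unavailable there).
#' @param p_diagnosis_symptomatic probability that a symptomatic participant
#'   carries at least one clinical diagnosis code (others qualify through
#'   their symptom scores alone).
#' @param movement_duration_range_min `c(min, max)` movement duration in
#'   minutes; the default 42-55 keeps every planted movement comfortably
#'   above the 30-minute trajectory threshold even after its first and
#'   last ~2 minutes are absorbed into the flanking stay points.
#' @param dwell_jitter_sd_m standard deviation (meters) of the positional
#'   jitter added to every sample; jitter magnitude is truncated at 25 m so
#'   dwell samples always stay within the 150-m stay-point radius.
#' @param session_duration_meanlog,session_duration_sdlog log-normal
#'   parameters of app-session durations in seconds.
#' @param base_lat,base_lon south-west corner of the area places are laid
#'   out in (WGS-84 degrees).
#' @param tz_offset fixed local-time offset in seconds for the whole cohort.
#' @param origin_day first day index of data collection (local days since
#'   epoch); only shifts timestamps.
#' @param seed integer RNG seed; the full raw dataset is a deterministic
#'   function of the config.
#' @return a validated list of class `sim_config`.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_participants = 50,
                       frac_symptomatic = 0.5,
                       days_range = c(4L, 43L),
                       sampling_period_stationary = 600,
                       sampling_period_moving = 60,
                       daily_trajectory_rate_symptomatic = 2,
                       daily_trajectory_rate_asymptomatic = 4,
                       n_places_range = c(3L, 8L),
                       place_spacing_m = 4000,
                       app_session_rate = 40,
                       app_category_weights = c(communication = 0.40,
                                                social = 0.25,
                                                entertainment = 0.20,
                                                other = 0.15),
                       demographics_params = list(age_mean = 54.2,
                                                  age_sd = 12.5,
                                                  edu_mean = 13.6,
                                                  edu_sd = 3.1,
                                                  p_female = 0.65),
                       missing_day_prob = 0.05,
                       frac_ios = 0.10,
                       p_diagnosis_symptomatic = 0.35,
                       movement_duration_range_min = c(42, 55),
                       dwell_jitter_sd_m = 10,
                       session_duration_meanlog = log(180),
                       session_duration_sdlog = 1,
                       base_lat = 52.1,
                       base_lon = 5.1,
                       tz_offset = 0,
                       origin_day = 19359L,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    frac_symptomatic = frac_symptomatic,
    days_range = as.integer(days_range),
    sampling_period_stationary = sampling_period_stationary,
    sampling_period_moving = sampling_period_moving,
    daily_trajectory_rate_symptomatic = daily_trajectory_rate_symptomatic,
    daily_trajectory_rate_asymptomatic = daily_trajectory_rate_asymptomatic,
    n_places_range = as.integer(n_places_range),
    place_spacing_m = place_spacing_m,
    app_session_rate = app_session_rate,
    app_category_weights = app_category_weights,
    demographics_params = demographics_params,
    missing_day_prob = missing_day_prob,
    frac_ios = frac_ios,
    p_diagnosis_symptomatic = p_diagnosis_symptomatic,
    movement_duration_range_min = movement_duration_range_min,
    dwell_jitter_sd_m = dwell_jitter_sd_m,
    session_duration_meanlog = session_duration_meanlog,
    session_duration_sdlog = session_duration_sdlog,
    base_lat = base_lat,
    base_lon = base_lon,
    tz_offset = tz_offset,
    origin_day = as.integer(origin_day),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  if (is.na(cfg$n_participants) || cfg$n_participants < 1)
    fail("n_participants must be a positive integer")
  if (cfg$frac_symptomatic < 0 || cfg$frac_symptomatic > 1)
    fail("frac_symptomatic must lie in [0, 1]")
  if (length(cfg$days_range) != 2 || any(is.na(cfg$days_range)) ||
      cfg$days_range[1] > cfg$days_range[2] ||
      cfg$days_range[1] < 1 || cfg$days_range[2] > 43)
    fail("days_range must be an increasing integer pair within [1, 43]")
  for (nm in c("daily_trajectory_rate_symptomatic",
               "daily_trajectory_rate_asymptomatic",
               "app_session_rate", "missing_day_prob", "frac_ios"))
    if (cfg[[nm]] < 0) fail(paste(nm, "must be nonnegative"))
  if (cfg$missing_day_prob > 1) fail("missing_day_prob must lie in [0, 1]")
  if (cfg$frac_ios > 1) fail("frac_ios must lie in [0, 1]")
  if (cfg$sampling_period_stationary <= 0 || cfg$sampling_period_moving <= 0)
    fail("sampling periods must be positive")
  w <- cfg$app_category_weights
  if (is.null(names(w)) || any(!nzchar(names(w))) || any(w < 0) ||
      abs(sum(w) - 1) > 1e-8)
    fail("app_category_weights must be named, nonnegative, and sum to 1")
  if (length(cfg$n_places_range) != 2 || cfg$n_places_range[1] < 1 ||
      cfg$n_places_range[1] > cfg$n_places_range[2])
    fail("n_places_range must be an increasing integer pair with min >= 1")
  if (cfg$place_spacing_m < 550)
    fail("place_spacing_m must be >= 550 so jittered places stay >= 450 m apart")
  dp <- cfg$demographics_params
  need <- c("age_mean", "age_sd", "edu_mean", "edu_sd", "p_female")
  if (!all(need %in% names(dp)))
    fail(paste("demographics_params must contain:", paste(need, collapse = ", ")))
  if (dp$p_female < 0 || dp$p_female > 1) fail("p_female must lie in [0, 1]")
  if (cfg$movement_duration_range_min[1] > cfg$movement_duration_range_min[2] ||
      cfg$movement_duration_range_min[1] <= 0)
    fail("movement_duration_range_min must be a positive increasing pair")
  if (cfg$dwell_jitter_sd_m < 0) fail("dwell_jitter_sd_m must be nonnegative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d participants (%.0f%% symptomatic), %d-%d days each\n",
              x$n_participants, 100 * x$frac_symptomatic,
              x$days_range[1], x$days_range[2]))
  cat(sprintf("  trajectory rates: symptomatic %.2f / asymptomatic %.2f per day\n",
              x$daily_trajectory_rate_symptomatic,
              x$daily_trajectory_rate_asymptomatic))
  cat(sprintf("  sampling: %ds stationary, %ds moving; app sessions %.0f/day\n",
              x$sampling_period_stationary, x$sampling_period_moving,
              x$app_session_rate))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
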