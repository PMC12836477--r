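# Independent oracles the implementation is checked against.

hav_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

# Exhaustive-window stay-point oracle: for every anchor i, the candidate
# window runs to the last j with all of p_i..p_j within dist_m of p_i
# (computed from the full O(n^2) distance table), and is accepted iff it
# spans min_dur_min; accepted windows consume their samples.
oracle_stay_points <- function(samples, dist_m = 150, min_dur_min = 30) {
  n <- nrow(samples)
  empty <- data.frame(centroid_lat = numeric(0), centroid_lon = numeric(0),
                      arrival_ts = numeric(0), departure_ts = numeric(0),
                      start_idx = integer(0), end_idx = integer(0))
  if (n < 2) return(empty)
  out <- list()
  i <- 1
  while (i < n) {
    d <- hav_m(samples$lat[i], samples$lon[i],
               samples$lat[(i + 1):n], samples$lon[(i + 1):n])
    exceed <- which(d > dist_m)
    j <- if (length(exceed)) i + exceed[1] else n + 1L
    if (samples$ts[j - 1] - samples$ts[i] >= min_dur_min * 60) {
      idx <- i:(j - 1)
      out[[length(out) + 1]] <- data.frame(
        centroid_lat = mean(samples$lat[idx]),
        centroid_lon = mean(samples$lon[idx]),
        arrival_ts = samples$ts[i], departure_ts = samples$ts[j - 1],
        start_idx = as.integer(i), end_idx = as.integer(j - 1))
      i <- j
    } else i <- i + 1L
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# AUROC as an explicit count of concordant positive/negative pairs with
# half credit for ties.
oracle_auroc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# A fuzzed synthetic day: random alternation of tight dwell clusters and
# wandering movement, with irregular sampling gaps.
random_day <- function(seed, n_max = 200) {
  set.seed(seed)
  n <- sample(10:n_max, 1)
  ts <- cumsum(sample(c(60, 120, 300, 600), n, replace = TRUE))
  lat <- numeric(n); lon <- numeric(n)
  cur <- c(52.1 + runif(1, -0.05, 0.05), 5.1 + runif(1, -0.05, 0.05))
  i <- 1
  while (i <= n) {
    len <- min(sample(2:40, 1), n - i + 1)
    if (runif(1) < 0.5) {                      # dwell: jitter < 60 m
      r <- runif(len, 0, 60); a <- runif(len, 0, 2 * pi)
      lat[i:(i + len - 1)] <- cur[1] + r * sin(a) / 111194.93
      lon[i:(i + len - 1)] <- cur[2] + r * cos(a) / (111194.93 * cos(cur[1] * pi / 180))
    } else {                                   # move: 30-400 m steps
      for (k in i:(i + len - 1)) {
        step <- runif(1, 30, 400); a <- runif(1, 0, 2 * pi)
        cur <- cur + c(step * sin(a) / 111194.93,
                       step * cos(a) / (111194.93 * cos(cur[1] * pi / 180)))
        lat[k] <- cur[1]; lon[k] <- cur[2]
      }
    }
    cur <- c(lat[i + len - 1], lon[i + len - 1])
    i <- i + len
  }
  data.frame(ts = ts, lat = lat, lon = lon)
}

# build location samples dwelling at (lat, lon) from t0 to t1
make_dwell <- function(lat, lon, t0, t1, period = 600, jitter_m = 0) {
  tt <- seq(t0, t1, by = period)
  if (jitter_m > 0) {
    r <- runif(length(tt), 0, jitter_m); a <- runif(length(tt), 0, 2 * pi)
    lat <- lat + r * sin(a) / 111194.93
    lon <- lon + r * cos(a) / (111194.93 * cos(lat[1] * pi / 180))
  }
  data.frame(ts = tt, lat = rep_len(lat, length(tt)), lon = rep_len(lon, length(tt)))
}

# constant-speed straight-line movement sampled every `period` seconds
make_move <- function(lat0, lon0, lat1, lon1, t0, t1, period = 60) {
  tt <- seq(t0, t1, by = period)
  f <- (tt - t0) / (t1 - t0)
  data.frame(ts = tt, lat = lat0 + f * (lat1 - lat0), lon = lon0 + f * (lon1 - lon0))
}

hm <- function(day, hms) {
  secs <- vapply(hms, function(h) {
    p <- as.numeric(strsplit(h, ":")[[1]])
    if (length(p) == 2) p <- c(p, 0)
    p[1] * 3600 + p[2] * 60 + p[3]
  }, numeric(1))
  unname(day * 86400 + secs)
}

# offset a (lat, lon) point by meters east/north
offset_m <- function(lat, lon, east_m, north_m) {
  c(lat = lat + north_m / 111194.93,
    lon = lon + east_m / (111194.93 * cos(lat * pi / 180)))
}

# minimal analysis-dataset stand-in for pipeline tests
fake_analysis <- function(n = 60, effect = 20, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  feats <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = rnorm(n, 54, 12), sex = rbinom(n, 1, 0.6),
    years_education = rnorm(n, 13, 3),
    n_trajectories_total = rnorm(n, 60 - effect * y, 10),
    noise1 = rnorm(n), noise2 = rnorm(n),
    stringsAsFactors = FALSE)
  list(features = feats, labels = setNames(y, feats$participant_id))
}
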