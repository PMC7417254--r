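# Movement indicators computed from collar fix streams: step lengths, daily
# net displacement, residency clusters (consecutive fixes within a 200 m
# radius) and duration of stay.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (via
#' [geosphere::distHaversine()]); sub-metre error at the 200 m scales this
#' package cares about, with no projection dependency.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (WGS84).
#' @return distance(s) in km; vectorized.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8) / 1000
}

#' Validate and order a fix table
#'
#' A trajectory is a data.frame with columns `female_id`, `t` (POSIXct, UTC),
#' `lon`, `lat`, holding the fixes of a single female in strictly increasing
#' time order. Nominal spacing is the collar's fix interval; gaps (failed
#' fixes) are allowed.
#'
#' @param x data.frame with the required columns.
#' @return the validated, time-sorted data.frame of class `"trajectory"`.
#' @export
as_trajectory <- function(x) {
  need <- c("female_id", "t", "lon", "lat")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("fix table missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(x$female_id)) > 1) stop("a trajectory holds a single female")
  if (!inherits(x$t, "POSIXct")) x$t <- as.POSIXct(x$t, tz = "UTC")
  attr(x$t, "tzone") <- "UTC"
  bad <- abs(x$lat) > 90 | abs(x$lon) > 180 | !is.finite(x$lon) | !is.finite(x$lat)
  if (any(bad)) stop(sum(bad), " fixes with out-of-range coordinates")
  x <- x[order(x$t), , drop = FALSE]
  if (anyDuplicated(as.numeric(x$t))) stop("duplicate timestamps within one female")
  rownames(x) <- NULL
  class(x) <- c("trajectory", "data.frame")
  x
}

#' Step lengths between consecutive fixes
#'
#' Net displacement per fix pair: the great-circle distance (km) between
#' consecutive GPS fixes. With fewer than two fixes the result is an empty
#' table, not an error.
#'
#' @param traj a trajectory (see [as_trajectory()]).
#' @return data.frame with `t_from`, `t_to`, `dist_km`; one row per
#'   consecutive fix pair (`n_fixes - 1` rows).
#' @export
step_lengths <- function(traj) {
  traj <- as_trajectory(traj)
  n <- nrow(traj)
  if (n < 2) {
    return(data.frame(t_from = as.POSIXct(character(), tz = "UTC"),
                      t_to = as.POSIXct(character(), tz = "UTC"),
                      dist_km = numeric()))
  }
  i <- seq_len(n - 1)
  data.frame(t_from = traj$t[i], t_to = traj$t[i + 1],
             dist_km = haversine_km(traj$lon[i], traj$lat[i],
                                    traj$lon[i + 1], traj$lat[i + 1]))
}

#' Daily net displacement
#'
#' Mean step distance per civil day: every step is assigned to the civil day
#' (default boundary UTC+2) of its *later* fix, and steps within each day are
#' averaged. Days with no step are omitted.
#'
#' @param traj a trajectory.
#' @param tz_offset_h UTC offset (hours) defining the civil day boundary.
#' @return data.frame with `day` (Date), `dnd_km` (mean step, km), `n_steps`.
#' @export
daily_net_displacement <- function(traj, tz_offset_h = 2) {
  st <- step_lengths(traj)
  if (nrow(st) == 0) return(data.frame(day = as.Date(character()),
                                       dnd_km = numeric(), n_steps = integer()))
  day <- civil_day(st$t_to, tz_offset_h)
  agg <- aggregate(st$dist_km, by = list(day = day),
                   FUN = function(v) c(mean(v), length(v)))
  data.frame(day = agg$day, dnd_km = agg$x[, 1], n_steps = as.integer(agg$x[, 2]))
}

#' Residency clusters: consecutive fixes within a fixed radius
#'
#' Greedy maximal-run scan: a fix extends the open cluster iff its distance
#' to the cluster anchor is at most `radius_m`; otherwise the cluster closes
#' (kept iff it holds at least `min_fixes` fixes) and a new one opens at that
#' fix. The default anchor is the running centroid, recomputed on each
#' accepted fix, which tolerates slow drift; `anchor = "first"` uses the
#' opening fix instead. Fix-schedule gaps (collar failures) never break a
#' cluster: only a received fix outside the radius does.
#'
#' @param traj a trajectory.
#' @param radius_m residency radius in metres (default 200, the scale of
#'   localized movement for this species).
#' @param min_fixes minimum fixes to keep a cluster (default 3, i.e. at least
#'   8 h of residency on a 4-h schedule).
#' @param anchor `"centroid"` (default) or `"first"`.
#' @return data.frame of class `"residency_clusters"`: `female_id`,
#'   `start_t`, `end_t`, `n_fixes`, `duration_days`, `lon`, `lat` (centroid),
#'   `max_radius_m` (largest accepted anchor distance).
#' @export
detect_clusters <- function(traj, radius_m = 200, min_fixes = 3,
                            anchor = c("centroid", "first")) {
  if (radius_m <= 0) stop("radius_m must be positive")
  anchor <- match.arg(anchor)
  traj <- as_trajectory(traj)
  cl <- .cluster_scan(traj$lon, traj$lat, radius_m, as.integer(min_fixes),
                      anchor == "centroid")
  out <- data.frame(
    female_id = rep(traj$female_id[1], nrow(cl)),
    start_t = traj$t[cl$start], end_t = traj$t[cl$end],
    n_fixes = cl$n_fixes,
    duration_days = as.numeric(traj$t[cl$end] - traj$t[cl$start], units = "days"),
    lon = cl$lon, lat = cl$lat, max_radius_m = cl$max_radius_m
  )
  if (nrow(out) == 0) {
    out$start_t <- as.POSIXct(out$start_t, tz = "UTC")
    out$end_t <- as.POSIXct(out$end_t, tz = "UTC")
  }
  class(out) <- c("residency_clusters", "data.frame")
  out
}

#' Duration of stay within a calendar month
#'
#' Summarizes cluster durations (consecutive days within the residency
#' radius) for the clusters of one female that overlap a given month.
#'
#' @param clusters output of [detect_clusters()] for a single female.
#' @param window month as `"YYYY-MM"`, a Date, or a month index; `NULL`
#'   summarizes all clusters.
#' @param tz_offset_h civil-time offset used to place cluster times in months.
#' @return list with `n`, `mean_days`, `se_days`, `max_days` (mean/SE/max are
#'   `NA` when no cluster overlaps the window).
#' @export
duration_of_stay <- function(clusters, window = NULL, tz_offset_h = 2) {
  d <- clusters$duration_days
  if (!is.null(window)) {
    w <- ym_parse(window)
    keep <- civil_ym(clusters$end_t, tz_offset_h) >= w &
      civil_ym(clusters$start_t, tz_offset_h) <= w
    d <- d[keep]
  }
  n <- length(d)
  list(n = n,
       mean_days = if (n) mean(d) else NA_real_,
       se_days = if (n > 1) stats::sd(d) / sqrt(n) else NA_real_,
       max_days = if (n) max(d) else NA_real_)
}
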