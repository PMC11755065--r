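# Dive detection from 1 Hz depth traces, foraging-trip segmentation, and the
# per-trip / per-deployment behavioural metrics.

#' Detect dives in a depth time series
#'
#' A dive is a maximal contiguous run of samples at or below `min_depth`
#' metres (depth positive downward) lasting at least `min_duration` seconds.
#' The threshold sits well above the 0.1 m sensor resolution and surface
#' splash noise; both knobs are exposed.
#'
#' @param depths Data frame with columns `time` (POSIXct or numeric seconds)
#'   and `depth_m` (>= 0).
#' @param min_depth Depth threshold in metres (default 1.0).
#' @param min_duration Minimum dive duration in seconds (default 3).
#' @param tz_offset_hours Colony local time minus UTC, used for the dive's
#'   hour of day (default -5).
#' @return Data frame of dives: `start, end, duration_min, max_depth_m,
#'   mean_depth_m, hour` (hour of local day of the dive start, 0-23).
#' @export
detect_dives <- function(depths, min_depth = 1.0, min_duration = 3,
                         tz_offset_hours = -5) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration_min = numeric(0), max_depth_m = numeric(0),
                      mean_depth_m = numeric(0), hour = integer(0))
  if (is.null(depths) || nrow(depths) == 0) return(empty)
  tt <- as.numeric(depths$time)
  if (any(diff(tt) <= 0)) stop("depth timestamps must be strictly increasing")
  if (any(depths$depth_m < 0)) stop("depths must be >= 0")
  wet <- depths$depth_m >= min_depth
  if (!any(wet)) return(empty)
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dt <- stats::median(diff(tt))
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    dur <- (i1 - i0 + 1) * dt
    if (dur < min_duration) return(NULL)
    seg <- depths$depth_m[i0:i1]
    hour_local <- floor(((tt[i0] + tz_offset_hours * 3600) %% 86400) / 3600)
    data.frame(start = tt[i0], end = tt[i1] + dt,
               duration_min = dur / 60,
               max_depth_m = max(seg), mean_depth_m = mean(seg),
               hour = as.integer(hour_local))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Segment foraging trips from a decoded step series
#'
#' Candidate excursions are maximal runs of steps farther than `min_dist_km`
#' from the colony; a candidate is kept as a foraging trip only if it lasts
#' longer than `min_duration_min` minutes (number of steps times the step
#' interval) and at least one dive overlaps its window. Excursions touching
#' the deployment boundary are flagged `partial`.
#'
#' @param series A `step_series` (see [regularize()]).
#' @param dives A [detect_dives()] output.
#' @param colony Length-2 (lon, lat) of the colony.
#' @param min_dist_km Colony-distance threshold (default 1).
#' @param min_duration_min Minimum trip duration in minutes (default 20).
#' @param interval Step interval in seconds (default 300).
#' @return Data frame of trips: `start, end, duration_h, first_idx, last_idx,
#'   max_dist_km, path_km, azimuth_deg, n_dives, partial`.
#' @export
segment_trips <- function(series, dives, colony, min_dist_km = 1,
                          min_duration_min = 20, interval = 300) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration_h = numeric(0), first_idx = integer(0),
                      last_idx = integer(0), max_dist_km = numeric(0),
                      path_km = numeric(0), azimuth_deg = numeric(0),
                      n_dives = integer(0), partial = logical(0))
  n <- nrow(series)
  if (n == 0) return(empty)
  away <- series$colonydist_km > min_dist_km
  if (!any(away)) return(empty)
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tt <- as.numeric(series$time)
  rows <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    dur_min <- (i1 - i0 + 1) * interval / 60
    if (dur_min <= min_duration_min) next
    w0 <- tt[i0]; w1 <- tt[i1] + interval
    nd <- if (nrow(dives)) sum(as.numeric(dives$start) < w1 &
                                 as.numeric(dives$end) > w0) else 0L
    if (nd < 1) next
    idx <- i0:i1
    summ <- trip_summary(idx, series, colony)
    rows[[length(rows) + 1]] <- data.frame(
      start = w0, end = w1, duration_h = dur_min / 60,
      first_idx = i0, last_idx = i1,
      max_dist_km = summ$max_dist_km, path_km = summ$path_km,
      azimuth_deg = summ$azimuth_deg, n_dives = as.integer(nd),
      partial = (i0 == 1L || i1 == n))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Per-trip summary metrics
#'
#' @param idx Integer indices of the trip's steps within `series`.
#' @param series The `step_series` the trip belongs to.
#' @param colony Length-2 (lon, lat).
#' @return List: `max_dist_km` (maximum colony distance), `path_km` (total
#'   distance traveled colony-to-colony: the great-circle step lengths over
#'   the trip's steps plus the approach and return legs), `duration_h`,
#'   `azimuth_deg` (initial bearing colony -> farthest point, in [0, 360)).
#' @export
trip_summary <- function(idx, series, colony) {
  cd <- series$colonydist_km[idx]
  far <- idx[which.max(cd)]
  az <- gc_bearing(colony, c(series$lon[far], series$lat[far]))
  path <- sum(series$step_km[idx])          # includes the approach leg
  last <- idx[length(idx)]
  if (last < nrow(series)) path <- path + series$step_km[last + 1]
  list(max_dist_km = max(cd), path_km = path,
       duration_h = length(idx) * 300 / 3600,
       azimuth_deg = as.numeric(az))
}

#' Mean dive depth for each hour of the day
#'
#' Averages dive mean depths by the hour of local day in which each dive
#' began; hours with no dives stay `NA` and propagate.
#'
#' @param dives A [detect_dives()] output (typically pooled over all birds of
#'   a year).
#' @return Named numeric vector of length 24 (names "0".."23").
#' @export
hourly_mean_depth <- function(dives) {
  if (is.null(dives) || nrow(dives) == 0)
    stop("no dives: hourly mean depth undefined")
  out <- rep(NA_real_, 24)
  names(out) <- as.character(0:23)
  agg <- tapply(dives$mean_depth_m, dives$hour, mean)
  out[names(agg)] <- agg
  out
}

#' Differential depth of a dive
#'
#' A dive's mean depth minus the hourly mean depth at the hour the dive
#' began; removes the diurnal cycle from depth comparisons. Absolute values
#' of the per-bird summaries are what enter pair-level models.
#'
#' @param dives A [detect_dives()] output.
#' @param hourly A [hourly_mean_depth()] vector.
#' @return Numeric vector of signed differential depths (m), one per dive.
#' @export
differential_depth <- function(dives, hourly) {
  h <- as.character(dives$hour)
  miss <- is.na(hourly[h])
  if (any(miss))
    stop("hourly mean depth undefined at hour(s): ",
         paste(unique(dives$hour[miss]), collapse = ", "))
  dives$mean_depth_m - unname(hourly[h])
}

#' Per-deployment behavioural metrics
#'
#' Per-trip metrics are averaged over the deployment's kept trips (SDs
#' computed alongside; a single-trip SD is reported as 0 with the
#' `single_trip` flag rather than dropped, so pair differencing keeps
#' complete rows). "Per day" rates divide by the real-valued deployment span
#' in days. Azimuth summaries are arithmetic means of bearings in [0, 360);
#' a warning is raised when a bird's trip bearings span more than 180
#' degrees.
#'
#' @param trips A [segment_trips()] output with at least one trip.
#' @param dives A [detect_dives()] output.
#' @param states Optional `state_path` for activity-time proportions.
#' @param span_hours Deployment span in hours.
#' @param hourly Optional [hourly_mean_depth()] vector for differential
#'   depth (defaults to this bird's own dives).
#' @return One-row data frame of deployment metrics.
#' @export
deployment_summary <- function(trips, dives, states = NULL, span_hours,
                               hourly = NULL) {
  if (is.null(trips) || nrow(trips) == 0)
    stop("no kept trips: bird excluded from deployment summaries")
  if (span_hours <= 0) stop("zero-length deployment")
  span_days <- span_hours / 24
  az <- trips$azimuth_deg
  if (length(az) > 1 && (max(az) - min(az)) > 180)
    warning("trip bearings span > 180 degrees; arithmetic azimuth mean ",
            "may be misleading (circular mean available)")
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  dd <- if (nrow(dives)) {
    hr <- if (is.null(hourly)) hourly_mean_depth(dives) else hourly
    differential_depth(dives, hr)
  } else numeric(0)
  m <- data.frame(
    n_trips = nrow(trips),
    max_dist_km = mean(trips$max_dist_km),
    sd_max_dist_km = sd0(trips$max_dist_km),
    total_dist_km = sum(trips$path_km),
    mean_trip_dist_km = mean(trips$path_km),
    sd_trip_dist_km = sd0(trips$path_km),
    trip_duration_h = mean(trips$duration_h),
    max_trip_duration_h = max(trips$duration_h),
    sd_trip_duration_h = sd0(trips$duration_h),
    azimuth_mean_deg = mean(az),
    azimuth_max_deg = max(az),
    azimuth_min_deg = min(az),
    sd_azimuth_deg = sd0(az),
    daily_dist_km = sum(trips$path_km) / span_days,
    trips_per_day = nrow(trips) / span_days,
    single_trip = nrow(trips) == 1,
    n_dives = nrow(dives),
    dives_per_day = nrow(dives) / span_days,
    max_dive_depth_m = if (nrow(dives)) max(dives$max_depth_m) else NA_real_,
    mean_dive_depth_m = if (nrow(dives)) mean(dives$mean_depth_m) else
      NA_real_,
    sd_dive_depth_m = sd0(dives$mean_depth_m),
    total_dive_duration_h = sum(dives$duration_min) / 60,
    max_dive_duration_min = if (nrow(dives)) max(dives$duration_min) else
      NA_real_,
    mean_dive_duration_min = if (nrow(dives)) mean(dives$duration_min) else
      NA_real_,
    sd_dive_duration_min = sd0(dives$duration_min),
    max_diff_depth_m = if (length(dd)) max(abs(dd)) else NA_real_,
    mean_diff_depth_m = if (length(dd)) mean(abs(dd)) else NA_real_,
    sd_diff_depth_m = sd0(abs(dd))
  )
  if (!is.null(states)) {
    tab <- table(factor(states$states, levels = HMM_STATES))
    prop <- as.numeric(tab) / sum(tab)
    m$prop_colony <- prop[1]; m$prop_diving <- prop[2]
    m$prop_flying <- prop[3]; m$prop_swimming <- prop[4]
  }
  m
}
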