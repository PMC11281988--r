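# Daily out-of-home mobility indicators. Two indicators are computed per
# mobility day: time out of home (TOH, cumulative minutes beyond the home
# buffer) and the convex-hull area of all of the day's fixes (CHull, km^2),
# plus a configurable stop/trip segmentation of the recorded time.

#' Is a fix out of home?
#'
#' A fix counts as out of home when its great-circle distance to the home
#' coordinate strictly exceeds the buffer radius; a fix at exactly the
#' buffer distance counts as at home (fixed convention for testability).
#'
#' @param lat,lon fix coordinate(s), degrees
#' @param home a [home_anchor]
#' @return logical vector
#' @export
is_out_of_home <- function(lat, lon, home) {
  stopifnot(inherits(home, "home_anchor"))
  d <- geodesic_distance(geo_point(lat, lon), home$pos)
  # nanometre tolerance so a fix at exactly the buffer distance stays
  # "home" regardless of floating-point noise in the haversine
  d > home$buffer_m + 1e-9
}

#' Time out of home for one mobility day
#'
#' TOH is the cumulative time per day spent beyond the home buffer. The
#' accumulation rule sums the durations of inter-fix intervals whose BOTH
#' endpoint fixes are out of home and whose length does not exceed
#' `max_gap_min` — recording holes longer than the gap cap contribute no
#' time, a conservative choice in the face of missing data.
#'
#' @param day a `track_day`
#' @param home a [home_anchor]
#' @param max_gap_min intervals longer than this (minutes) are never counted
#' @return minutes (fractional allowed), >= 0
#' @export
time_out_of_home <- function(day, home, max_gap_min = 10) {
  f <- day$fixes
  if (is.null(f) || nrow(f) < 2L) {
    if (is.null(f) || nrow(f) == 0L) warning("no fixes; TOH is 0")
    else warning("single fix; TOH is 0")
    return(0)
  }
  out <- is_out_of_home(f$lat, f$lon, home)
  dt_min <- as.numeric(diff(f$t), units = "mins")
  n <- nrow(f)
  qual <- out[-n] & out[-1] & dt_min <= max_gap_min
  sum(dt_min[qual])
}

#' Daily convex-hull area in square kilometres
#'
#' All of the day's GPS fixes (including at-home fixes) are projected into
#' a local azimuthal equal-area plane centred at the day's centroid; the
#' area of their convex hull is returned in km^2. Days with fewer than
#' three non-collinear fixes have area 0.
#'
#' @param day a `track_day`
#' @return km^2
#' @export
daily_convex_hull_km2 <- function(day) {
  f <- day$fixes
  if (is.null(f) || nrow(f) < 3L) return(0)
  centroid <- geo_point(mean(f$lat), mean(f$lon))
  xy <- project_local(geo_point(f$lat, f$lon), centroid)
  hull <- convex_hull(xy)
  if (hull$degenerate) return(0)
  polygon_area(hull$vertices) / 1e6
}

#' Stop/trip segmentation of a mobility day
#'
#' A reconstruction of a dwell-based classifier: maximal runs of fixes that
#' all stay within `stop_radius_m` of the run's medoid and span at least
#' `min_dwell_min` become stops; the spans between stops (and before the
#' first / after the last stop, when they contain movement) become trips.
#' Segments tile the recorded time of the day without overlap.
#'
#' The parameters are defaults of this reconstruction, not values published
#' for the study's optimized classifier.
#'
#' @param day a `track_day`
#' @param stop_radius_m dwell radius, metres
#' @param min_dwell_min minimum dwell duration, minutes
#' @return data.frame with columns `kind` ("stop"/"trip"), `start`, `end`
#'   (POSIXct), `anchor_lat`, `anchor_lon` (stop medoid or trip midpoint)
#' @export
segment_stops_trips <- function(day, stop_radius_m = 50, min_dwell_min = 5) {
  f <- day$fixes
  empty <- data.frame(kind = character(0),
                      start = as.POSIXct(character(0)),
                      end = as.POSIXct(character(0)),
                      anchor_lat = numeric(0), anchor_lon = numeric(0))
  if (is.null(f) || nrow(f) < 2L) return(empty)
  n <- nrow(f)
  pts <- geo_point(f$lat, f$lon)
  centroid <- geo_point(mean(f$lat), mean(f$lon))
  xy <- as.matrix(project_local(pts, centroid))

  medoid_of <- function(idx) {
    sub <- xy[idx, , drop = FALSE]
    d2 <- as.matrix(stats::dist(sub))
    idx[which.min(rowSums(d2))]
  }
  within_radius <- function(idx) {
    med <- xy[medoid_of(idx), ]
    d <- sqrt((xy[idx, 1] - med[1])^2 + (xy[idx, 2] - med[2])^2)
    all(d <= stop_radius_m)
  }

  # greedy scan: grow a candidate dwell while the radius condition holds
  stops <- list()
  i <- 1L
  while (i < n) {
    j <- i
    while (j < n && within_radius(i:(j + 1L))) j <- j + 1L
    span_min <- as.numeric(difftime(f$t[j], f$t[i], units = "mins"))
    if (j > i && span_min >= min_dwell_min) {
      stops[[length(stops) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }

  segs <- list()
  add_seg <- function(kind, i0, i1) {
    mid <- if (kind == "stop") medoid_of(i0:i1) else i0 + (i1 - i0) %/% 2L
    segs[[length(segs) + 1L]] <<- data.frame(
      kind = kind, start = f$t[i0], end = f$t[i1],
      anchor_lat = f$lat[mid], anchor_lon = f$lon[mid])
  }
  cur <- 1L
  for (s in stops) {
    if (s[1] > cur) add_seg("trip", cur, s[1])
    add_seg("stop", s[1], s[2])
    cur <- s[2]
  }
  if (cur < n) add_seg("trip", cur, n)
  do.call(rbind, segs)
}

#' Compute the per-day indicator table for a set of track days
#'
#' @param days list of `track_day` (from [split_days])
#' @param homes named list of [home_anchor] keyed by person id
#' @param max_gap_min TOH gap cap, minutes
#' @return data.frame with one row per person-day: `person_id`,
#'   `mobility_date`, `toh_min`, `chull_km2`, `n_fixes`, `coverage_hours`,
#'   `valid`. Indicators are computed for invalid days too (flagged), so
#'   they can be inspected; modelling uses valid days only.
#' @export
daily_mobility <- function(days, homes, max_gap_min = 10) {
  rows <- lapply(days, function(day) {
    home <- homes[[day$person_id]]
    if (is.null(home)) return(NULL)
    toh <- suppressWarnings(time_out_of_home(day, home, max_gap_min))
    data.frame(person_id = day$person_id,
               mobility_date = day$mobility_date,
               toh_min = toh,
               chull_km2 = daily_convex_hull_km2(day),
               n_fixes = nrow(day$fixes),
               coverage_hours = day$coverage_hours,
               valid = day$valid,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    warning(skipped, " track day(s) skipped: no home anchor for the person")
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(person_id = character(0), mobility_date = as.Date(character(0)),
                      toh_min = numeric(0), chull_km2 = numeric(0),
                      n_fixes = integer(0), coverage_hours = integer(0),
                      valid = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary of the daily indicators
#'
#' Mean and sample SD of TOH and CHull over valid days only, matching the
#' descriptive rows of a study's Table-1-style report.
#'
#' @param mobility data.frame from [daily_mobility]
#' @return data.frame with columns `indicator`, `mean`, `sd`, `n_days`,
#'   `sd_defined`
#' @export
summarize_mobility <- function(mobility) {
  v <- mobility[mobility$valid, , drop = FALSE]
  if (nrow(v) == 0L) stop("no valid days to summarize")
  one <- function(name, x) {
    data.frame(indicator = name, mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               n_days = length(x), sd_defined = length(x) > 1L)
  }
  out <- rbind(one("toh_min", v$toh_min), one("chull_km2", v$chull_km2))
  rownames(out) <- NULL
  out
}

#' Write the indicator table as CSV
#' @param mobility data.frame from [daily_mobility]
#' @param path output path
#' @export
write_mobility_csv <- function(mobility, path) {
  utils::write.csv(mobility, path, row.names = FALSE)
  invisible(path)
}
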