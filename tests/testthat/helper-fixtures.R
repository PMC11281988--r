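# Shared fixtures and independent oracles used across the suite.

TZ <- "Europe/Berlin"

# Place fixes by planar (x, y) metres around a home coordinate and stamp
# them with regular timestamps. Radial planar distance equals geodesic
# distance to ~1e-10 m at sub-km scales in the equal-area projection.
make_day <- function(x, y, start = "2022-07-01 09:00:00",
                     interval_s = 60, home = NULL,
                     person_id = "P1", tz = TZ) {
  if (is.null(home)) home <- home_anchor(person_id, 52.6, 12.4)
  g <- unproject_local(data.frame(x = x, y = y), home$pos)
  t0 <- as.POSIXct(start, tz = tz)
  times <- t0 + (seq_along(x) - 1L) * interval_s
  fixes <- data.frame(person_id = person_id, t = times,
                      lat = g$lat, lon = g$lon, accuracy_m = NA_real_,
                      stringsAsFactors = FALSE)
  day <- list(person_id = person_id,
              mobility_date = mobility_date_of(t0, tz),
              fixes = fixes, tz = tz)
  day$coverage_hours <- coverage_hours(day)
  day$valid <- is_valid_day(day)
  class(day) <- "track_day"
  day
}

# As make_day but with explicit timestamps (POSIXct vector).
make_day_at <- function(x, y, times, home = NULL, person_id = "P1", tz = TZ) {
  if (is.null(home)) home <- home_anchor(person_id, 52.6, 12.4)
  g <- unproject_local(data.frame(x = x, y = y), home$pos)
  fixes <- data.frame(person_id = person_id, t = times,
                      lat = g$lat, lon = g$lon, accuracy_m = NA_real_,
                      stringsAsFactors = FALSE)
  day <- list(person_id = person_id,
              mobility_date = mobility_date_of(times[1], tz),
              fixes = fixes, tz = tz)
  day$coverage_hours <- coverage_hours(day)
  day$valid <- is_valid_day(day)
  class(day) <- "track_day"
  day
}

# O(n^3)-flavoured brute-force convex hull oracle, independent of the
# monotone-chain implementation: an ordered pair (i, j) is a hull edge iff
# every other point lies strictly to its left; edges are chained into the
# polygon and the area taken by the shoelace formula.
brute_hull_area <- function(x, y) {
  pts <- unique(data.frame(x = x, y = y))
  n <- nrow(pts)
  if (n < 3L) return(0)
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cr <- (pts$x[j] - pts$x[i]) * (pts$y - pts$y[i]) -
        (pts$y[j] - pts$y[i]) * (pts$x - pts$x[i])
      others <- setdiff(seq_len(n), c(i, j))
      if (all(cr[others] > 0)) edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  if (length(edges) < 3L) return(0)   # collinear configuration
  e <- do.call(rbind, edges)
  ord <- integer(nrow(e))
  ord[1] <- e[1, 1]
  cur <- e[1, 2]
  for (k in 2:nrow(e)) {
    ord[k] <- cur
    cur <- e[e[, 1] == cur, 2]
  }
  abs(sum(pts$x[ord] * pts$y[c(ord[-1], ord[1])] -
            pts$x[c(ord[-1], ord[1])] * pts$y[ord])) / 2
}

# Minimal complete person table for design/fit tests.
make_persons <- function(ids, education = "high") {
  n <- length(ids)
  data.frame(person_id = ids,
             age = seq(76, 86, length.out = n),
             sex_female = rep_len(c(1, 0), n),
             cohabiting = rep_len(c(1, 1, 0), n),
             education = rep_len(education, n),
             ksk12 = seq(35, 55, length.out = n),
             psk12 = seq(50, 64, length.out = n),
             health_literacy = seq(30, 48, length.out = n),
             social_network_satisfaction = seq(8, 10, length.out = n),
             active_driving = rep_len(c(1, 1, 1, 0), n),
             stringsAsFactors = FALSE)
}

make_env_table <- function(ids) {
  n <- length(ids)
  data.frame(person_id = ids,
             intersection_density = rep_len(c(40, 90, 120), n),
             green_share_pct = seq(5, 35, length.out = n),
             pt_reach_count = rep_len(0:4, n),
             health_reach_count = rep_len(0:2, n),
             sidewalk_quality = rep_len(0:3, n),
             utilization_score = seq(0.5, 2.5, length.out = n),
             subjective_access = rep_len(c(1, 2, 3), n),
             stringsAsFactors = FALSE)
}

# A small square green ring (half-side r metres) at planar offset (cx, cy)
# from `origin`.
square_green <- function(cx, cy, r, origin, category = "park") {
  g <- unproject_local(data.frame(x = cx + c(-r, r, r, -r),
                                  y = cy + c(-r, -r, r, r)), origin)
  list(ring = data.frame(lat = g$lat, lon = g$lon), category = category)
}
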