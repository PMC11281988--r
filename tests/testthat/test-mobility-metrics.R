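test_that("out-of-home test uses a strict 50 m boundary", {
  home <- home_anchor("P1", 52.6, 12.4)
  at_home <- unproject_local(data.frame(x = 0, y = 0), home$pos)
  near <- unproject_local(data.frame(x = 0, y = 49), home$pos)
  far <- unproject_local(data.frame(x = 0, y = 51), home$pos)
  # exactly on the geodesic 50 m circle: boundary counts as home
  exact <- geo_point(52.6 + (50 / EARTH_RADIUS_M) * 180 / pi, 12.4)
  expect_false(is_out_of_home(at_home$lat, at_home$lon, home))
  expect_false(is_out_of_home(near$lat, near$lon, home))
  expect_true(is_out_of_home(far$lat, far$lon, home))
  expect_false(is_out_of_home(exact$lat, exact$lon, home))

  # widening the buffer never flips home -> out
  wide <- home_anchor("P1", 52.6, 12.4, buffer_m = 100)
  expect_false(is_out_of_home(far$lat, far$lon, wide))
})

test_that("TOH hand-computed values: outing, recording hole, all-home", {
  home <- home_anchor("P1", 52.6, 12.4)
  # fixes every 60 s, 09:00-13:00; out of home exactly 10:00-12:00
  n <- 241
  off <- ifelse(seq_len(n) >= 61 & seq_len(n) <= 181, 500, 0)
  day <- make_day(off, rep(0, n), start = "2022-07-01 09:00:00", home = home)
  expect_equal(time_out_of_home(day, home), 120)

  # same outing with a 30-min hole 10:30-11:00: gap > cap, 90 min remain
  keep <- !(seq_len(n) > 91 & seq_len(n) < 121)
  t0 <- as.POSIXct("2022-07-01 09:00:00", tz = TZ)
  day_hole <- make_day_at(off[keep], rep(0, sum(keep)),
                          t0 + (which(keep) - 1) * 60, home = home)
  expect_equal(time_out_of_home(day_hole, home), 90)

  day_home <- make_day(rep(0, 100), rep(0, 100), home = home)
  expect_equal(time_out_of_home(day_home, home), 0)

  expect_warning(z <- time_out_of_home(make_day(0, 0, home = home), home),
                 "single fix")
  expect_equal(z, 0)
})

test_that("TOH properties: monotone in buffer, bounded by recorded span", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 120
    x <- cumsum(rnorm(n, sd = 40)); y <- cumsum(rnorm(n, sd = 40))
    day <- make_day(x, y)
    tohs <- vapply(c(25, 50, 100, 200, 400), function(b) {
      time_out_of_home(day, home_anchor("P1", 52.6, 12.4, buffer_m = b))
    }, 0)
    expect_true(all(diff(tohs) <= 1e-9))
    span <- as.numeric(diff(range(day$fixes$t)), units = "mins")
    expect_lte(tohs[1], span + 1e-9)
  }
})

test_that("daily hull area: degenerate, constructed square, oracle equality", {
  home <- home_anchor("P1", 52.6, 12.4)
  expect_equal(daily_convex_hull_km2(make_day(rep(0, 10), rep(0, 10))), 0)
  # collinear fixes (along one meridian) -> degenerate -> 0
  expect_equal(daily_convex_hull_km2(make_day(rep(0, 10),
                                              seq(0, 1800, 200))), 0)

  # a traced geodesic square of side ~1000 m -> 1 km^2 within 0.5 %
  side <- seq(0, 1000, by = 100)
  sx <- c(side, rep(1000, 11), rev(side), rep(0, 11))
  sy <- c(rep(0, 11), side, rep(1000, 11), rev(side))
  expect_lt(abs(daily_convex_hull_km2(make_day(sx, sy)) - 1), 0.005)

  set.seed(32)
  x <- rnorm(30, sd = 1500); y <- rnorm(30, sd = 1500)
  day <- make_day(x, y)
  got <- daily_convex_hull_km2(day)
  # oracle in the day's own projected plane
  ctr <- geo_point(mean(day$fixes$lat), mean(day$fixes$lon))
  xy <- project_local(geo_point(day$fixes$lat, day$fixes$lon), ctr)
  expect_equal(got, brute_hull_area(xy$x, xy$y) / 1e6, tolerance = 1e-9)
})

test_that("hull area is invariant to fix order, duplicates and interior fixes", {
  set.seed(33)
  x <- rnorm(25, sd = 1000); y <- rnorm(25, sd = 1000)
  t0 <- as.POSIXct("2022-07-01 09:00:00", tz = TZ)
  base <- make_day(x, y)
  a0 <- daily_convex_hull_km2(base)
  perm <- sample(25)
  expect_equal(daily_convex_hull_km2(make_day(x[perm], y[perm])), a0)
  expect_equal(daily_convex_hull_km2(make_day(c(x, x[1:5]), c(y, y[1:5]))), a0)
  # an interior fix changes nothing; an exterior one never shrinks the hull
  expect_equal(daily_convex_hull_km2(make_day(c(x, mean(x)), c(y, mean(y)))), a0)
  expect_gte(daily_convex_hull_km2(make_day(c(x, 6000), c(y, 0))), a0)
})

test_that("stop/trip segmentation matches hand classification", {
  home <- home_anchor("P1", 52.6, 12.4)
  # 30 min at one point -> one stop spanning the recorded time
  d1 <- make_day(rep(0, 31), rep(0, 31))
  s1 <- segment_stops_trips(d1)
  expect_equal(s1$kind, "stop")
  expect_equal(as.numeric(difftime(s1$end, s1$start, units = "mins")), 30)

  # dwell A (20 min), straight 2 km walk (20 min), dwell B (20 min)
  xa <- rep(0, 20)
  xw <- seq(100, 2000, by = 100)
  xb <- rep(2000, 20)
  d2 <- make_day(c(xa, xw, xb), rep(0, 60))
  s2 <- segment_stops_trips(d2)
  expect_equal(s2$kind, c("stop", "trip", "stop"))
  # segments tile recorded time without overlap
  expect_equal(s2$start[-1], s2$end[-nrow(s2)])
  expect_equal(s2$start[1], d2$fixes$t[1])
  expect_equal(s2$end[nrow(s2)], d2$fixes$t[nrow(d2$fixes)])

  # continuous walk, no dwell >= 5 min -> single trip
  d3 <- make_day(seq(0, 5000, by = 100), seq(0, 2500, by = 50))
  s3 <- segment_stops_trips(d3)
  expect_equal(s3$kind, "trip")

  expect_equal(nrow(segment_stops_trips(make_day(0, 0))), 0L)
})

test_that("mobility summary: means, SDs, invalid exclusion, degenerate SD", {
  mob <- data.frame(person_id = "P1", mobility_date = as.Date("2022-07-01") + 0:3,
                    toh_min = c(100, 200, 300, 900),
                    chull_km2 = c(1, 2, 3, 99), n_fixes = 10,
                    coverage_hours = c(10, 10, 10, 2),
                    valid = c(TRUE, TRUE, TRUE, FALSE))
  s <- summarize_mobility(mob)
  expect_equal(s$mean[s$indicator == "toh_min"], 200)
  expect_equal(s$sd[s$indicator == "toh_min"], 100)
  expect_equal(s$n_days, c(3, 3))

  one <- mob[1, ]
  s1 <- summarize_mobility(one)
  expect_equal(s1$sd, c(0, 0))
  expect_false(any(s1$sd_defined))

  expect_error(summarize_mobility(mob[mob$valid == FALSE, ]), "no valid days")
})

test_that("daily_mobility assembles the indicator table and flags invalid days", {
  home <- home_anchor("P1", 52.6, 12.4)
  t0 <- as.POSIXct("2022-07-01 08:00:00", tz = TZ)
  # 9 hours of fixes every 10 min, outing in the middle
  n <- 55
  out <- ifelse(seq_len(n) > 20 & seq_len(n) <= 40, 300, 0)
  fixes <- make_day_at(out, rep(0, n), t0 + (seq_len(n) - 1) * 600,
                       home = home)$fixes
  days <- split_days(fixes, tz = TZ)
  mob <- daily_mobility(days, list(P1 = home))
  expect_equal(nrow(mob), 1L)
  expect_true(mob$valid)
  expect_equal(mob$n_fixes, n)
  expect_gt(mob$toh_min, 0)

  expect_warning(daily_mobility(days, list(OTHER = home)), "skipped")
})
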