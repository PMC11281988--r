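grid_scene <- function(n_streets = 3, spacing = 500, seed = 101) {
  cfg <- sim_config(n_persons = 2, seed = seed, grid_spacing_m = spacing,
                    n_streets = n_streets, green_density = 0, poi_density = 0)
  simulate_environment(cfg)
}

test_that("intersection density: 3x3 grid has 5 nodes of degree >= 3", {
  env <- grid_scene(3, 500)
  home <- home_anchor("P1", env$origin$lat, env$origin$lon)
  # degree map of a 3x3 grid: 4 corners deg 2, 4 edge midpoints deg 3,
  # 1 centre deg 4 -> 5 qualifying intersections, all within 1500 m
  expect_equal(intersection_density(home, env$ways, radius_m = 1500), 5L)
  expect_equal(intersection_density(home, list()), 0L)
})

test_that("intersection density respects the radius", {
  env <- grid_scene(3, 500)
  # home displaced so the grid centre sits 1600 m away: with radius 1500
  # the centre node (deg 4, 1600 m) and the far edge-midpoint nodes
  # (1676 m, 2100 m) are excluded; only the near midpoint (1100 m) remains
  off <- unproject_local(data.frame(x = 1600, y = 0), env$origin)
  home <- home_anchor("P1", off$lat, off$lon)
  expect_equal(intersection_density(home, env$ways, radius_m = 1500), 1L)
  # monotone non-decreasing in radius
  r <- c(600, 1100, 1600, 2200, 3000)
  counts <- vapply(r, function(ri) {
    intersection_density(home, env$ways, radius_m = ri)
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("green share: empty, full disc, analytic half-plane, union", {
  origin <- geo_point(52.6, 12.4)
  home <- home_anchor("P1", 52.6, 12.4)
  expect_equal(green_share(home, list()), 0)

  full <- square_green(0, 0, 2000, origin)
  expect_equal(green_share(home, list(full)), 100)

  # half-plane through the home point (big rectangle covering y > 0)
  half <- square_green(0, 5000, 5000, origin)
  expect_lt(abs(green_share(home, list(half)) - 50), 0.5)

  # two identical polygons: union never counts area twice
  patch <- square_green(100, 50, 150, origin)
  expect_equal(green_share(home, list(patch, patch)),
               green_share(home, list(patch)))
})

test_that("green share stays in [0, 100] on random scenes", {
  set.seed(41)
  origin <- geo_point(52.6, 12.4)
  home <- home_anchor("P1", 52.6, 12.4)
  for (rep in 1:20) {
    polys <- lapply(seq_len(sample(0:4, 1)), function(i) {
      square_green(runif(1, -800, 800), runif(1, -800, 800),
                   runif(1, 20, 400), origin)
    })
    gs <- green_share(home, polys, grid_n = 120)
    expect_gte(gs, 0)
    expect_lte(gs, 100)
  }
})

test_that("reach counts apply the speed-derived radius", {
  origin <- geo_point(52.6, 12.4)
  home <- home_anchor("P1", 52.6, 12.4)
  mk_poi <- function(dist, category) {
    g <- unproject_local(data.frame(x = dist, y = 0), origin)
    data.frame(lat = g$lat, lon = g$lon, category = category)
  }
  pois <- rbind(mk_poi(800, "bus_stop"), mk_poi(1000, "bus_stop"),
                mk_poi(400, "pharmacy"))
  # speed 1 m/s, 15 min -> 900 m radius: only the 800 m stop counts
  expect_equal(reach_count(home, pois, "bus_stop", speed_m_s = 1.0), 1L)
  expect_equal(reach_count(home, pois, "rail_station", speed_m_s = 1.0), 0L)
  expect_error(reach_count(home, pois, "bus_stop", speed_m_s = 0), "positive")

  # non-decreasing in speed
  counts <- vapply(c(0.5, 0.9, 1.2, 2.0), function(v) {
    reach_count(home, pois, c("bus_stop", "pharmacy"), speed_m_s = v)
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("questionnaire scores follow the published codings", {
  expect_equal(utilization_score(rep(0, 7)), 0)
  expect_equal(utilization_score(rep("haeufiger", 7)), 3)
  expect_equal(utilization_score(c(0, 1, 3)), 4 / 3)
  expect_equal(utilization_score(c("nie", "1 im Monat", NA)), 0.5)
  expect_true(is.na(utilization_score(rep(NA_real_, 7))))
  expect_error(utilization_score("sometimes"), "unknown")
  expect_error(utilization_score(c(0, 5)), "range")

  expect_equal(subjective_access_score(3, 3), 3)
  expect_equal(subjective_access_score(1, 2), 1.5)
  expect_equal(subjective_access_score(0, NA), 0)
  expect_true(is.na(subjective_access_score(NA, NA)))
  expect_error(subjective_access_score(4, 1), "0-3")

  expect_equal(sidewalk_quality_score("sehr schlecht"), 0)
  expect_equal(sidewalk_quality_score("sehr gut"), 3)
  expect_equal(sidewalk_quality_score(2), 2)
  # bijective label -> code mapping
  labels <- c("sehr schlecht", "eher schlecht", "eher gut", "sehr gut")
  expect_equal(vapply(labels, sidewalk_quality_score, 0, USE.NAMES = FALSE), 0:3)
  expect_error(sidewalk_quality_score(7), "range")
})

test_that("exposures are translation-equivariant", {
  env <- grid_scene(3, 400)
  shift <- c(25000, -18000)   # metres
  move <- function(lat, lon) {
    xy <- project_local(geo_point(lat, lon), env$origin)
    unproject_local(data.frame(x = xy$x + shift[1], y = xy$y + shift[2]),
                    env$origin)
  }
  ways2 <- lapply(env$ways, function(w) {
    g <- move(w$polyline$lat, w$polyline$lon)
    list(polyline = data.frame(lat = g$lat, lon = g$lon),
         walkable = w$walkable, way_id = w$way_id)
  })
  patch <- square_green(200, -100, 180, env$origin)
  gp <- move(patch$ring$lat, patch$ring$lon)
  patch2 <- list(ring = data.frame(lat = gp$lat, lon = gp$lon),
                 category = "park")
  poi <- unproject_local(data.frame(x = 700, y = 100), env$origin)
  pois1 <- data.frame(lat = poi$lat, lon = poi$lon, category = "bus_stop")
  poi2 <- move(pois1$lat, pois1$lon)
  pois2 <- data.frame(lat = poi2$lat, lon = poi2$lon, category = "bus_stop")

  home1 <- home_anchor("P1", env$origin$lat, env$origin$lon)
  h2 <- move(env$origin$lat, env$origin$lon)
  home2 <- home_anchor("P1", h2$lat, h2$lon)

  expect_equal(intersection_density(home1, env$ways),
               intersection_density(home2, ways2))
  expect_equal(green_share(home1, list(patch), grid_n = 150),
               green_share(home2, list(patch2), grid_n = 150),
               tolerance = 1e-6)
  expect_equal(reach_count(home1, pois1, "bus_stop", 1.0),
               reach_count(home2, pois2, "bus_stop", 1.0))
})

test_that("environment layers round-trip through GeoJSON", {
  cfg <- sim_config(n_persons = 2, seed = 7, n_streets = 3,
                    green_density = 5, poi_density = 5)
  layers <- simulate_environment(cfg)
  path <- tempfile(fileext = ".geojson")
  write_env_geojson(layers, path)
  back <- read_env_geojson(path)
  expect_length(back$ways, length(layers$ways))
  expect_length(back$green, length(layers$green))
  expect_equal(nrow(back$pois), nrow(layers$pois))
  expect_equal(back$ways[[1]]$polyline$lat, layers$ways[[1]]$polyline$lat)
  expect_equal(sort(back$pois$category), sort(layers$pois$category))

  home <- home_anchor("P1", 52.6, 12.4)
  expect_equal(intersection_density(home, back$ways),
               intersection_density(home, layers$ways))
})

test_that("env_profile assembles one row per person and merges surveys", {
  cfg <- sim_config(n_persons = 2, seed = 7, n_streets = 3,
                    green_density = 2, poi_density = 3)
  layers <- simulate_environment(cfg)
  homes <- simulate_homes(cfg, layers)
  survey <- data.frame(person_id = names(homes),
                       sidewalk_quality = c(2, 3),
                       utilization_score = c(1.5, 0.5),
                       subjective_access = c(2.5, 3))
  prof <- env_profile(homes, layers, survey = survey, speed_m_s = 1.0)
  expect_equal(nrow(prof), 2L)
  expect_true(all(c("intersection_density", "green_share_pct",
                    "pt_reach_count", "health_reach_count",
                    "sidewalk_quality") %in% names(prof)))
  expect_equal(prof$sidewalk_quality, c(2, 3))
})
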