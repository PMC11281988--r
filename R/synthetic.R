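# Seeded generators for a synthetic study world: a cohort with realistic
# covariate marginals, a gridded built environment, day-level Poisson
# outcomes from a known random-intercept model, and GPS day trajectories
# with controllable time out of home. Every generator is a pure function
# of (config, seed), so the whole pipeline can be tested against known
# ground truth.

#' Simulation configuration
#'
#' Defaults describe the cohort the package targets: community-dwelling
#' adults aged 75+ in a rural region. Covariate marginals (means/SDs and
#' proportions) default to the descriptive values of such a cohort:
#' age 81.5 (4.1) truncated at 75, 56.1 % women, 57.1 % cohabiting,
#' health literacy index 40.6 (5.8) on 0-50, physical / mental
#' health-related quality of life 43.9 (11.3) / 58.4 (4.9) on 0-100,
#' social-network satisfaction 9.6 (1.0) on 0-10, 88.2 % active drivers,
#' education low/middle/high in proportions 5:85:122.
#'
#' @param n_persons cohort size (>= 2)
#' @param days_per_person days of GPS recording per person (default 7)
#' @param seed integer seed; every generator derives its randomness from it
#' @param beta named or plain numeric vector of true fixed effects; the
#'   first element is the intercept, the last the day-counter effect
#' @param tau00 true random-intercept variance (>= 0)
#' @param walking_speed_m_s cohort mean gait speed (default 1.0 m/s)
#' @param fix_interval_s GPS sampling interval (default 60 s)
#' @param gps_noise_sd_m isotropic GPS jitter SD in metres (default 5)
#' @param home_buffer_m home buffer radius (default 50)
#' @param grid_spacing_m street-grid spacing of the synthetic town
#' @param n_streets streets per direction of the grid
#' @param green_density green polygons per km^2 (0 disables green areas)
#' @param poi_density points of interest per km^2 and category
#' @param covariates list overriding individual marginals (see defaults)
#' @return a `sim_config` list
#' @export
sim_config <- function(n_persons = 200, days_per_person = 7, seed = 1,
                       beta = c(intercept = log(300), counter = 0),
                       tau00 = 0.5,
                       walking_speed_m_s = 1.0, fix_interval_s = 60,
                       gps_noise_sd_m = 5, home_buffer_m = 50,
                       grid_spacing_m = 500, n_streets = 9,
                       green_density = 3, poi_density = 2,
                       covariates = list()) {
  stopifnot(n_persons >= 2, days_per_person >= 1, tau00 >= 0)
  defaults <- list(
    age = list(mean = 81.5, sd = 4.1, lower = 75, upper = 105),
    female = 0.561, cohabiting = 0.571, active_driving = 0.882,
    education = c(low = 5, middle = 85, high = 122) / 212,
    health_literacy = list(mean = 40.6, sd = 5.8, lower = 0, upper = 50),
    ksk12 = list(mean = 43.9, sd = 11.3, lower = 0, upper = 100),
    psk12 = list(mean = 58.4, sd = 4.9, lower = 0, upper = 100),
    social_network_satisfaction = list(mean = 9.6, sd = 1.0,
                                       lower = 0, upper = 10))
  cov <- utils::modifyList(defaults, covariates)
  structure(list(n_persons = n_persons, days_per_person = days_per_person,
                 seed = as.integer(seed), beta = beta, tau00 = tau00,
                 walking_speed_m_s = walking_speed_m_s,
                 fix_interval_s = fix_interval_s,
                 gps_noise_sd_m = gps_noise_sd_m,
                 home_buffer_m = home_buffer_m,
                 grid_spacing_m = grid_spacing_m, n_streets = n_streets,
                 green_density = green_density, poi_density = poi_density,
                 covariates = cov),
            class = "sim_config")
}

# Truncated-normal draws whose TRUNCATED mean matches `mean`: the location
# of the underlying normal is shifted (numerically) so inclusion bounds
# such as age >= 75 do not bias the marginal mean away from its target.
rnorm_trunc_matched <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd; b <- (upper - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  mu <- if (is.finite(lower) || is.finite(upper)) {
    stats::uniroot(function(m) trunc_mean(m) - mean,
                   interval = c(mean - 6 * sd, mean + 6 * sd))$root
  } else {
    mean
  }
  u <- stats::runif(n, stats::pnorm(lower, mu, sd), stats::pnorm(upper, mu, sd))
  stats::qnorm(u, mu, sd)
}

#' Simulate the person-level covariate table
#'
#' Independent draws from the configured marginals: mean-matched truncated
#' normals for continuous scores, Bernoulli for binaries, a categorical
#' draw for the education tiers. Reproducible from the seed.
#'
#' @param config a [sim_config]
#' @return data.frame in the layout [build_day_design] expects
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cv <- config$covariates
  n <- config$n_persons
  draw <- function(spec) {
    rnorm_trunc_matched(n, spec$mean, spec$sd, spec$lower, spec$upper)
  }
  data.frame(
    person_id = sprintf("P%04d", seq_len(n)),
    age = draw(cv$age),
    sex_female = stats::rbinom(n, 1, cv$female),
    cohabiting = stats::rbinom(n, 1, cv$cohabiting),
    education = sample(names(cv$education), n, replace = TRUE,
                       prob = cv$education),
    ksk12 = draw(cv$ksk12),
    psk12 = draw(cv$psk12),
    health_literacy = draw(cv$health_literacy),
    social_network_satisfaction = draw(cv$social_network_satisfaction),
    active_driving = stats::rbinom(n, 1, cv$active_driving),
    stringsAsFactors = FALSE)
}

#' Simulate environment layers (street grid, green areas, POIs)
#'
#' Builds a rectangular walkable street grid (shared vertices at every
#' crossing), square green polygons and category-labelled points of
#' interest at the configured densities, centred at a reference coordinate
#' in rural Brandenburg. Deterministic given the config seed.
#'
#' @param config a [sim_config]
#' @param center_lat,center_lon town centre (defaults: 52.6 N, 12.4 E)
#' @param categories POI category vocabulary
#' @return list with `ways`, `green`, `pois` (the [env_profile] layout)
#' @export
simulate_environment <- function(config, center_lat = 52.6, center_lon = 12.4,
                                 categories = c("bus_stop", "rail_station",
                                                "pharmacy", "gp_practice",
                                                "hospital", "shop")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  origin <- geo_point(center_lat, center_lon)
  k <- config$n_streets
  s <- config$grid_spacing_m
  half <- (k - 1) / 2 * s
  coords <- seq(-half, half, by = s)
  to_geo <- function(x, y) unproject_local(data.frame(x = x, y = y), origin)

  ways <- list()
  for (i in seq_len(k)) {   # horizontal streets, vertices at each crossing
    g <- to_geo(coords, rep(coords[i], k))
    ways[[length(ways) + 1L]] <- list(
      polyline = data.frame(lat = g$lat, lon = g$lon),
      walkable = TRUE, way_id = sprintf("H%02d", i))
  }
  for (j in seq_len(k)) {   # vertical streets
    g <- to_geo(rep(coords[j], k), coords)
    ways[[length(ways) + 1L]] <- list(
      polyline = data.frame(lat = g$lat, lon = g$lon),
      walkable = TRUE, way_id = sprintf("V%02d", j))
  }

  extent_km2 <- (2 * half / 1000)^2
  green <- list()
  n_green <- stats::rpois(1, config$green_density * extent_km2)
  green_cats <- c("garden", "park", "forest", "recreation")
  if (n_green > 0) {
    for (g in seq_len(n_green)) {
      cx <- stats::runif(1, -half, half)
      cy <- stats::runif(1, -half, half)
      r <- stats::runif(1, 50, 250)   # half-side of the square patch
      gg <- to_geo(cx + c(-r, r, r, -r), cy + c(-r, -r, r, r))
      green[[length(green) + 1L]] <- list(
        ring = data.frame(lat = gg$lat, lon = gg$lon),
        category = sample(green_cats, 1))
    }
  }

  pois <- data.frame(lat = numeric(0), lon = numeric(0),
                     category = character(0))
  for (cat in categories) {
    n_poi <- stats::rpois(1, config$poi_density * extent_km2)
    if (n_poi == 0) next
    px <- stats::runif(n_poi, -half, half)
    py <- stats::runif(n_poi, -half, half)
    pg <- to_geo(px, py)
    pois <- rbind(pois, data.frame(lat = pg$lat, lon = pg$lon,
                                   category = cat, stringsAsFactors = FALSE))
  }
  rownames(pois) <- NULL
  list(ways = ways, green = green, pois = pois,
       origin = origin, half_extent_m = half)
}

#' Simulate homes for a cohort on the synthetic map
#'
#' Uniform home locations within the inner two thirds of the town extent.
#'
#' @param config a [sim_config]
#' @param env layers from [simulate_environment]
#' @return named list of [home_anchor]
#' @export
simulate_homes <- function(config, env) {
  set.seed(config$seed + 2L)
  n <- config$n_persons
  lim <- env$half_extent_m * 2 / 3
  xy <- data.frame(x = stats::runif(n, -lim, lim),
                   y = stats::runif(n, -lim, lim))
  g <- unproject_local(xy, env$origin)
  homes <- lapply(seq_len(n), function(i) {
    home_anchor(sprintf("P%04d", i), g$lat[i], g$lon[i],
                buffer_m = config$home_buffer_m)
  })
  names(homes) <- vapply(homes, `[[`, character(1), "person_id")
  homes
}

#' Simulate day-level outcome counts from the generating model
#'
#' Draws person intercepts b_i ~ N(0, tau00), forms the linear predictor
#' eta = beta0 + x' beta + beta_counter * counter + b_i and samples
#' y ~ Poisson(exp(eta)). The design columns used are taken from the names
#' of `config$beta` (any subset of the covariate columns plus `intercept`
#' and `counter`).
#'
#' @param cohort data.frame from [simulate_cohort]
#' @param config a [sim_config]
#' @param xmat optional explicit design matrix (n_persons rows) for the
#'   non-intercept, non-counter effects; overrides cohort columns
#' @return list with `days` (data.frame `person_id`, `counter`, `eta`, `y`)
#'   and `truth` (`beta`, `tau00`, `b` per person)
#' @export
simulate_daily_counts <- function(cohort, config, xmat = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n <- nrow(cohort)
  d <- config$days_per_person
  beta <- config$beta
  nm <- names(beta)
  if (is.null(nm)) {
    nm <- c("intercept", paste0("x", seq_len(length(beta) - 2L)), "counter")
    names(beta) <- nm
  }
  mid <- setdiff(nm, c("intercept", "counter"))
  Xp <- if (length(mid) == 0L) {
    matrix(0, n, 0)
  } else if (!is.null(xmat)) {
    as.matrix(xmat[, mid, drop = FALSE])
  } else {
    as.matrix(cohort[, mid, drop = FALSE])
  }
  b <- stats::rnorm(n, 0, sqrt(config$tau00))
  eta_p <- beta[["intercept"]] +
    (if (ncol(Xp)) as.numeric(Xp %*% beta[mid]) else 0) + b
  counter <- rep(seq_len(d), times = n)
  eta <- rep(eta_p, each = d) +
    (if ("counter" %in% nm) beta[["counter"]] * counter else 0)
  if (any(eta > 30)) {
    stop("linear predictor overflow (eta > 30); choose smaller beta")
  }
  y <- stats::rpois(n * d, exp(eta))
  days <- data.frame(person_id = rep(cohort$person_id, each = d),
                     counter = counter, eta = eta, y = y,
                     stringsAsFactors = FALSE)
  list(days = days,
       truth = list(beta = beta, tau00 = config$tau00, b = b))
}

#' Simulate one GPS mobility day with a target time out of home
#'
#' Builds a fix sequence at the configured sampling interval: a home dwell
#' from 04:00, one or more excursions to random waypoints beyond the home
#' buffer whose out-of-home fix span totals the target, and a return home,
#' padded so the day always covers at least 8 distinct hours (so it passes
#' the validity filter). Optional isotropic Gaussian jitter emulates GPS
#' noise. The recomputed TOH of the result is within two sampling
#' intervals of the target.
#'
#' @param target_toh_min target minutes out of home, 0 to 1080 (18 h)
#' @param home a [home_anchor]
#' @param config a [sim_config]
#' @param date the mobility date (Date)
#' @param tz study timezone
#' @param rng_seed seed for waypoints and jitter (default derived from
#'   config seed and the date)
#' @return a `track_day`
#' @export
simulate_trajectory <- function(target_toh_min, home, config,
                                date = as.Date("2022-07-01"),
                                tz = "Europe/Berlin", rng_seed = NULL) {
  stopifnot(inherits(home, "home_anchor"), inherits(config, "sim_config"))
  if (target_toh_min < 0 || target_toh_min > 18 * 60) {
    stop("target TOH must be within 0..1080 minutes")
  }
  iv <- config$fix_interval_s
  if (target_toh_min > 0 && target_toh_min * 60 < 2 * iv) {
    stop("target TOH infeasible at the configured fix interval")
  }
  if (is.null(rng_seed)) {
    rng_seed <- (config$seed + as.integer(date)) %% .Machine$integer.max
  }
  set.seed(rng_seed)

  day_start <- as.POSIXct(paste(format(date), "04:00:00"), tz = tz)
  span_h <- max(12, ceiling(target_toh_min / 60) + 2)
  times <- seq(day_start, by = iv, length.out = span_h * 3600 / iv + 1)

  n <- length(times)
  rel <- as.numeric(difftime(times, day_start, units = "secs"))
  # excursion window centred in the day; fixes strictly inside it are out
  out_dur <- target_toh_min * 60
  t0 <- (span_h * 3600 - out_dur) / 2
  out_idx <- integer(0)
  if (out_dur > 0) {
    first_out <- which(rel >= t0)[1]
    out_idx <- seq(first_out, length.out = out_dur / iv + 1)
    out_idx <- out_idx[out_idx <= n]
  }

  home_xy <- c(0, 0)
  x <- rep(home_xy[1], n)
  y <- rep(home_xy[2], n)
  if (length(out_idx) > 1L) {
    # waypoints well beyond the buffer; piecewise-constant-velocity walk
    n_wp <- sample(2:4, 1)
    # waypoints within a 120-degree cone so legs between them never pass
    # within the home buffer (chord-to-origin distance >= 400 cos 60 = 200 m)
    base_ang <- stats::runif(1, 0, 2 * pi)
    ang <- base_ang + stats::runif(n_wp, -pi / 3, pi / 3)
    rad <- stats::runif(n_wp, 400, 4000)
    wx <- rad * cos(ang); wy <- rad * sin(ang)
    k <- length(out_idx)
    leg <- cut(seq_len(k), breaks = n_wp, labels = FALSE)
    for (w in seq_len(n_wp)) {
      sel <- out_idx[leg == w]
      m <- length(sel)
      if (m == 0) next
      # walk toward the waypoint then dwell there
      prev <- if (w == 1) c(wx[1], wy[1]) else c(wx[w - 1], wy[w - 1])
      frac <- pmin(seq_len(m) / max(3, m %/% 4), 1)
      x[sel] <- prev[1] + frac * (wx[w] - prev[1])
      y[sel] <- prev[2] + frac * (wy[w] - prev[2])
    }
  }
  if (config$gps_noise_sd_m > 0) {
    x <- x + stats::rnorm(n, 0, config$gps_noise_sd_m)
    y <- y + stats::rnorm(n, 0, config$gps_noise_sd_m)
  }
  g <- unproject_local(data.frame(x = x, y = y), home$pos)
  fixes <- data.frame(person_id = home$person_id, t = times,
                      lat = g$lat, lon = g$lon, accuracy_m = NA_real_,
                      stringsAsFactors = FALSE)
  day <- list(person_id = home$person_id, mobility_date = date,
              fixes = fixes, tz = tz)
  day$coverage_hours <- coverage_hours(day)
  day$valid <- is_valid_day(day)
  class(day) <- "track_day"
  day
}

#' Simulate a full GPS study: trajectories for every person-day
#'
#' Combines [simulate_daily_counts] (interpreting the counts as target TOH
#' minutes, capped at 18 h) with [simulate_trajectory] and returns the raw
#' fix table plus ground truth.
#'
#' @param config a [sim_config]
#' @param homes named list of [home_anchor] (e.g. from [simulate_homes])
#' @param cohort data.frame from [simulate_cohort]
#' @param start_date first mobility date
#' @param tz study timezone
#' @return list with `fixes` (GPS table), `targets` (person-day targets)
#'   and `truth`
#' @export
simulate_gps_study <- function(config, homes, cohort,
                               start_date = as.Date("2022-07-01"),
                               tz = "Europe/Berlin") {
  sim <- simulate_daily_counts(cohort, config)
  days <- sim$days
  days$target_toh_min <- pmin(days$y, 18 * 60)
  days$mobility_date <- start_date + days$counter - 1L
  fixes <- vector("list", nrow(days))
  for (i in seq_len(nrow(days))) {
    day <- simulate_trajectory(days$target_toh_min[i],
                               homes[[days$person_id[i]]], config,
                               date = days$mobility_date[i], tz = tz,
                               rng_seed = (config$seed + 7919L * i) %%
                                 .Machine$integer.max)
    fixes[[i]] <- day$fixes
  }
  list(fixes = do.call(rbind, fixes), targets = days, truth = sim$truth)
}

#' Write a GPS fix table as CSV (the dialect [read_gps_table] reads)
#' @param fixes data.frame with `person_id`, `t`, `lat`, `lon`
#' @param path output path
#' @export
write_gps_csv <- function(fixes, path) {
  out <- data.frame(person_id = fixes$person_id,
                    timestamp = format(fixes$t, "%Y-%m-%dT%H:%M:%S%z"),
                    lat = fixes$lat, lon = fixes$lon)
  if (!is.null(fixes$accuracy_m) && any(!is.na(fixes$accuracy_m))) {
    out$accuracy_m <- fixes$accuracy_m
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write home anchors as CSV (the dialect [read_homes_table] reads)
#' @param homes named list of [home_anchor]
#' @param path output path
#' @export
write_homes_csv <- function(homes, path) {
  out <- do.call(rbind, lapply(homes, function(h) {
    data.frame(person_id = h$person_id, lat = h$pos$lat, lon = h$pos$lon,
               buffer_m = h$buffer_m)
  }))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
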