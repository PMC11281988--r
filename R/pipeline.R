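# Orchestration: simulate -> indicators -> environment -> fit -> report,
# as a configured, logged workflow with a machine-readable run manifest.

#' Assemble a run configuration
#'
#' Flat key/value configuration for the pipeline commands; any field can be
#' overridden per call. Paths are resolved at run time.
#'
#' @param gps,homes,env_geojson,covariates,survey input paths
#' @param out_dir output directory (created if absent)
#' @param timezone study timezone
#' @param buffer_m home-buffer radius, metres
#' @param validity_rule `"distinct_hours"` or `"cumulative"`
#' @param min_hours validity threshold (hours)
#' @param max_gap_min TOH gap cap (minutes)
#' @param intersection_radius_m,green_radius_m exposure radii
#' @param walking_speed_m_s cohort mean gait speed
#' @param response `"toh"` or `"chull"` (run_fit fits both; this sets the
#'   primary one for single-model calls)
#' @param seed integer seed
#' @return a `run_config` list
#' @export
run_config <- function(gps = NULL, homes = NULL, env_geojson = NULL,
                       covariates = NULL, survey = NULL, out_dir = ".",
                       timezone = "Europe/Berlin", buffer_m = 50,
                       validity_rule = "distinct_hours", min_hours = 8,
                       max_gap_min = 10,
                       intersection_radius_m = 1500, green_radius_m = 500,
                       walking_speed_m_s = 1.0,
                       response = "toh", seed = 1L) {
  structure(list(gps = gps, homes = homes, env_geojson = env_geojson,
                 covariates = covariates, survey = survey, out_dir = out_dir,
                 timezone = timezone, buffer_m = buffer_m,
                 validity_rule = validity_rule, min_hours = min_hours,
                 max_gap_min = max_gap_min,
                 intersection_radius_m = intersection_radius_m,
                 green_radius_m = green_radius_m,
                 walking_speed_m_s = walking_speed_m_s,
                 response = response, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a flat key=value config file into a [run_config]
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are
#' rejected. Values are coerced to the type of the default.
#'
#' @param path config file
#' @param ... overrides applied after the file
#' @return a `run_config`
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  base <- run_config()
  vals <- list()
  for (p in kv) {
    if (length(p) != 2L) stop("malformed config line: ", paste(p, collapse = "="))
    key <- p[1]
    if (!key %in% names(base)) stop("unknown config key: ", key)
    proto <- base[[key]]
    vals[[key]] <- if (is.numeric(proto) || is.integer(proto)) {
      as.numeric(p[2])
    } else p[2]
  }
  do.call(run_config, utils::modifyList(vals, list(...)))
}

manifest_add <- function(manifest, key, value) {
  manifest[[key]] <- value
  manifest
}

write_manifest <- function(manifest, config, path) {
  manifest$parameters <- config[!vapply(config, is.null, logical(1))]
  manifest$package_version <- as.character(utils::packageVersion("lifespace"))
  manifest$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Compute the per-person-day indicator table from raw inputs
#'
#' Reads the GPS fix table and home anchors, splits fixes into
#' 03:00-anchored mobility days, applies the validity filter and computes
#' TOH and CHull per day. Persons without a home anchor are skipped and
#' logged. Writes `mobility.csv` and a run manifest to the output
#' directory.
#'
#' @param config a [run_config] with `gps` and `homes` set
#' @return the indicator data.frame, invisibly written to
#'   `out_dir/mobility.csv`
#' @export
run_metrics <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fixes <- read_gps_table(config$gps, tz = config$timezone)
  homes <- read_homes_table(config$homes, buffer_m = config$buffer_m)
  days <- split_days(fixes, tz = config$timezone)
  for (i in seq_along(days)) {
    days[[i]]$coverage_hours <- coverage_hours(days[[i]], rule = config$validity_rule,
                                               max_gap_min = config$max_gap_min)
    days[[i]]$valid <- is_valid_day(days[[i]], min_hours = config$min_hours)
  }
  skipped <- setdiff(unique(vapply(days, `[[`, character(1), "person_id")),
                     names(homes))
  mobility <- withCallingHandlers(
    daily_mobility(days, homes, max_gap_min = config$max_gap_min),
    warning = function(w) {
      message("run_metrics: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  out_path <- file.path(config$out_dir, "mobility.csv")
  write_mobility_csv(mobility, out_path)
  manifest <- list(command = "metrics",
                   n_fixes = nrow(fixes),
                   n_persons = length(unique(fixes$person_id)),
                   n_days = length(days),
                   n_valid_days = sum(mobility$valid),
                   persons_skipped_no_home = skipped)
  write_manifest(manifest, config,
                 file.path(config$out_dir, "metrics_manifest.json"))
  message(sprintf("run_metrics: %d persons, %d days (%d valid) -> %s",
                  manifest$n_persons, manifest$n_days,
                  manifest$n_valid_days, out_path))
  invisible(mobility)
}

#' Compute per-person environment profiles from map layers
#'
#' @param config a [run_config] with `homes`, `env_geojson` and optionally
#'   `survey` (CSV of scored questionnaire variables) set
#' @return the profile data.frame, written to `out_dir/environment.csv`
#' @export
run_environment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  homes <- read_homes_table(config$homes, buffer_m = config$buffer_m)
  layers <- read_env_geojson(config$env_geojson)
  survey <- if (!is.null(config$survey)) {
    utils::read.csv(config$survey, stringsAsFactors = FALSE)
  } else NULL
  prof <- env_profile(homes, layers, survey = survey,
                      speed_m_s = config$walking_speed_m_s,
                      intersection_radius_m = config$intersection_radius_m,
                      green_radius_m = config$green_radius_m)
  out_path <- file.path(config$out_dir, "environment.csv")
  utils::write.csv(prof, out_path, row.names = FALSE)
  manifest <- list(command = "environment", n_persons = nrow(prof),
                   n_ways = length(layers$ways),
                   n_green = length(layers$green),
                   n_pois = nrow(layers$pois))
  write_manifest(manifest, config,
                 file.path(config$out_dir, "environment_manifest.json"))
  invisible(prof)
}

#' Fit the day-level mixed models and write coefficient reports
#'
#' Fits the Poisson random-intercept GLMM for both indicators (TOH and
#' CHull) on the valid person-days, writing per-model coefficient CSVs and
#' an aligned plain-text report.
#'
#' @param config a [run_config]; `covariates` must point to the person
#'   table CSV, and `out_dir` must contain `mobility.csv` and
#'   `environment.csv` (or pass the tables directly)
#' @param mobility,persons,env optional in-memory tables overriding the
#'   CSV inputs
#' @return named list of `glmm_fit` (`toh`, `chull`)
#' @export
run_fit <- function(config, mobility = NULL, persons = NULL, env = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(mobility)) {
    mobility <- utils::read.csv(file.path(config$out_dir, "mobility.csv"),
                                stringsAsFactors = FALSE)
    mobility$mobility_date <- as.Date(mobility$mobility_date)
  }
  if (is.null(persons)) {
    persons <- utils::read.csv(config$covariates, stringsAsFactors = FALSE)
  }
  if (is.null(env)) {
    env <- utils::read.csv(file.path(config$out_dir, "environment.csv"),
                           stringsAsFactors = FALSE)
  }
  fits <- list()
  report <- character(0)
  for (resp in c("toh", "chull")) {
    design <- build_day_design(mobility, persons, env, response = resp)
    fit <- fit_poisson_glmm(design)
    fits[[resp]] <- fit
    tab <- coefficient_table(fit)
    utils::write.csv(tab, file.path(config$out_dir,
                                    sprintf("coefficients_%s.csv", resp)),
                     row.names = FALSE)
    report <- c(report, format_fit_report(fit, label = toupper(resp)), "")
  }
  writeLines(report, file.path(config$out_dir, "fit_report.txt"))
  manifest <- list(command = "fit",
                   n_persons = fits$toh$n_persons,
                   n_obs = fits$toh$n_obs,
                   converged = list(toh = fits$toh$converged,
                                    chull = fits$chull$converged))
  write_manifest(manifest, config, file.path(config$out_dir, "fit_manifest.json"))
  invisible(fits)
}

#' Descriptive cohort summary (Table-1 style)
#'
#' n (%) for categorical variables, M (SD) for continuous ones, including
#' the mobility-indicator rows over valid days. Percentages are printed to
#' one decimal, matching epidemiological table conventions.
#'
#' @param persons person covariate data.frame
#' @param mobility optional indicator table for the TOH/CHull rows
#' @param env optional environment profile table
#' @return data.frame with columns `variable`, `value` (formatted string)
#' @export
run_descriptives <- function(persons, mobility = NULL, env = NULL) {
  n <- nrow(persons)
  rows <- list()
  add <- function(variable, value) {
    rows[[length(rows) + 1L]] <<- data.frame(variable = variable,
                                             value = value,
                                             stringsAsFactors = FALSE)
  }
  n_pct <- function(k) sprintf("%d (%s)", k, formatC(100 * k / n, format = "f",
                                                     digits = 1))
  m_sd <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) {
      return(sprintf("%s (SD undefined)", formatC(mean(x), format = "f", digits = 1)))
    }
    sprintf("%s (%s)", formatC(mean(x), format = "f", digits = 1),
            formatC(stats::sd(x), format = "f", digits = 1))
  }
  add("N", as.character(n))
  add("Age, M (SD)", m_sd(persons$age))
  add("Female, n (%)", n_pct(sum(persons$sex_female == 1)))
  for (lev in c("low", "middle", "high")) {
    add(sprintf("Education %s, n (%%)", lev),
        n_pct(sum(persons$education == lev)))
  }
  add("Cohabiting, n (%)", n_pct(sum(persons$cohabiting == 1)))
  add("Active driving, n (%)", n_pct(sum(persons$active_driving == 1)))
  add("Health literacy, M (SD)", m_sd(persons$health_literacy))
  add("KSK-12, M (SD)", m_sd(persons$ksk12))
  add("PSK-12, M (SD)", m_sd(persons$psk12))
  add("Social-network satisfaction, M (SD)",
      m_sd(persons$social_network_satisfaction))
  if (!is.null(mobility)) {
    v <- mobility[mobility$valid, , drop = FALSE]
    add("TOH (min), M (SD)", m_sd(v$toh_min))
    add("CHull (km2), M (SD)", m_sd(v$chull_km2))
  }
  if (!is.null(env)) {
    add("Intersection density (1500 m), M (SD)", m_sd(env$intersection_density))
    add("Green share % (500 m), M (SD)", m_sd(env$green_share_pct))
    add("Transit stops in 15-min reach, M (SD)", m_sd(env$pt_reach_count))
    add("Health facilities in 15-min reach, M (SD)", m_sd(env$health_reach_count))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `metrics`, `environment`, `fit`, `report`.
#' Flags: `--config`, `--gps`, `--homes`, `--env`, `--covariates`,
#' `--survey`, `--out`, `--response {toh,chull}`, `--seed`, `--timezone`,
#' `--n-persons` (simulate only). Designed to be called from an Rscript
#' wrapper (see `inst/cli/lifespace.R`).
#'
#' @param args character vector of arguments (default: the command line)
#' @return exit status, invisibly
#' @export
lifespace_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: lifespace <simulate|metrics|environment|fit|report> [flags]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  flags <- parse_cli_flags(args[-1])
  cfg_args <- list()
  if (!is.null(flags$config)) {
    cfg <- read_run_config(flags$config)
  } else {
    cfg <- run_config()
  }
  map <- c(gps = "gps", homes = "homes", env = "env_geojson",
           covariates = "covariates", survey = "survey", out = "out_dir",
           response = "response", timezone = "timezone")
  for (fl in names(map)) {
    if (!is.null(flags[[fl]])) cfg[[map[[fl]]]] <- flags[[fl]]
  }
  if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)

  status <- 0L
  if (cmd == "simulate") {
    n <- if (!is.null(flags[["n-persons"]])) as.integer(flags[["n-persons"]]) else 20L
    sc <- sim_config(n_persons = n, seed = cfg$seed,
                     home_buffer_m = cfg$buffer_m,
                     walking_speed_m_s = cfg$walking_speed_m_s)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    cohort <- simulate_cohort(sc)
    layers <- simulate_environment(sc)
    homes <- simulate_homes(sc, layers)
    study <- simulate_gps_study(sc, homes, cohort)
    utils::write.csv(cohort, file.path(cfg$out_dir, "covariates.csv"),
                     row.names = FALSE)
    write_gps_csv(study$fixes, file.path(cfg$out_dir, "gps.csv"))
    write_homes_csv(homes, file.path(cfg$out_dir, "homes.csv"))
    write_env_geojson(layers, file.path(cfg$out_dir, "environment.geojson"))
    write_manifest(list(command = "simulate", n_persons = n,
                        n_fixes = nrow(study$fixes)),
                   cfg, file.path(cfg$out_dir, "simulate_manifest.json"))
    message("simulate: wrote covariates.csv, gps.csv, homes.csv, environment.geojson")
  } else if (cmd == "metrics") {
    run_metrics(cfg)
  } else if (cmd == "environment") {
    run_environment(cfg)
  } else if (cmd == "fit") {
    run_fit(cfg)
  } else if (cmd == "report") {
    persons <- utils::read.csv(cfg$covariates, stringsAsFactors = FALSE)
    mob_path <- file.path(cfg$out_dir, "mobility.csv")
    env_path <- file.path(cfg$out_dir, "environment.csv")
    mobility <- if (file.exists(mob_path)) {
      utils::read.csv(mob_path, stringsAsFactors = FALSE)
    } else NULL
    env <- if (file.exists(env_path)) {
      utils::read.csv(env_path, stringsAsFactors = FALSE)
    } else NULL
    tab <- run_descriptives(persons, mobility, env)
    utils::write.csv(tab, file.path(cfg$out_dir, "descriptives.csv"),
                     row.names = FALSE)
    cat(sprintf("%-42s %s\n", tab$variable, tab$value), sep = "")
  } else {
    message("unknown subcommand: ", cmd)
    status <- 2L
  }
  invisible(status)
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}
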