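# GPS ingestion and the mobility-day calendar: fixes are attributed to the
# 03:00-anchored day so that post-midnight activity counts toward the
# preceding day, and a day is valid when at least 8 hours carry data.

#' Read a table of GPS fixes
#'
#' Accepts either a CSV with columns `person_id,timestamp,lat,lon[,accuracy_m]`
#' (ISO-8601 timestamps) or a GPX 1.1 file with one or more `<trk>` tracks
#' (one person per file; id taken from `person_id` or the file name).
#' Fixes are returned sorted by person and time; exact duplicates (same
#' person, same timestamp) keep the first occurrence so that re-reading is
#' order-stable.
#'
#' @param path path to a `.csv` or `.gpx` file
#' @param tz study timezone used to interpret and store timestamps
#' @param person_id person identifier for GPX input (default: file name
#'   without extension)
#' @param max_accuracy_m optional accuracy cutoff in metres; fixes with a
#'   worse (larger) reported accuracy are dropped. `NULL` (default) keeps
#'   everything — the validity rules of the study specify no accuracy filter.
#' @return data.frame with columns `person_id` (character), `t` (POSIXct),
#'   `lat`, `lon`, `accuracy_m` (NA when absent)
#' @export
read_gps_table <- function(path, tz = "Europe/Berlin", person_id = NULL,
                           max_accuracy_m = NULL) {
  if (!file.exists(path)) stop("GPS input not found: ", path)
  ext <- tolower(tools::file_ext(path))
  fixes <- if (ext == "gpx") {
    read_gpx_fixes(path, tz = tz, person_id = person_id)
  } else {
    read_csv_fixes(path, tz = tz)
  }
  if (nrow(fixes) == 0L) {
    warning("no GPS fixes read from ", path)
    return(fixes)
  }
  if (!is.null(max_accuracy_m)) {
    keep <- is.na(fixes$accuracy_m) | fixes$accuracy_m <= max_accuracy_m
    fixes <- fixes[keep, , drop = FALSE]
  }
  fixes <- fixes[order(fixes$person_id, fixes$t), , drop = FALSE]
  dup <- duplicated(fixes[, c("person_id", "t")])
  fixes <- fixes[!dup, , drop = FALSE]
  rownames(fixes) <- NULL
  fixes
}

read_csv_fixes <- function(path, tz) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("person_id", "timestamp", "lat", "lon")
  if (!all(need %in% names(raw))) {
    stop("GPS CSV must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(data.frame(person_id = character(0),
                      t = as.POSIXct(character(0), tz = tz),
                      lat = numeric(0), lon = numeric(0),
                      accuracy_m = numeric(0)))
  }
  t <- parse_iso8601(raw$timestamp, tz = tz)
  if (anyNA(t)) {
    stop("unparseable timestamp in row(s) ",
         paste(utils::head(which(is.na(t)), 5), collapse = ", "),
         " of ", path)
  }
  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))
  bad <- is.na(lat) | is.na(lon) | lat < -90 | lat > 90 | lon < -180 | lon > 180
  if (any(bad)) {
    stop("invalid coordinate in row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), " of ", path)
  }
  acc <- if ("accuracy_m" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$accuracy_m))
  } else {
    rep(NA_real_, nrow(raw))
  }
  data.frame(person_id = as.character(raw$person_id), t = t,
             lat = lat, lon = lon, accuracy_m = acc,
             stringsAsFactors = FALSE)
}

# ISO-8601 with optional fractional seconds and offset/Z; 'T' or space.
parse_iso8601 <- function(x, tz) {
  x <- gsub("T", " ", x, fixed = TRUE)
  x <- sub("Z$", " +0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", " \\1\\2", x)
  has_offset <- grepl("[+-][0-9]{4}$", x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  if (any(has_offset)) {
    out[has_offset] <- as.POSIXct(x[has_offset],
                                  format = "%Y-%m-%d %H:%M:%OS %z", tz = tz)
  }
  if (any(!has_offset)) {
    out[!has_offset] <- as.POSIXct(x[!has_offset],
                                   format = "%Y-%m-%d %H:%M:%OS", tz = tz)
  }
  out
}

read_gpx_fixes <- function(path, tz, person_id = NULL) {
  if (is.null(person_id)) {
    person_id <- tools::file_path_sans_ext(basename(path))
  }
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  pts <- xml2::xml_find_all(doc, ".//g:trkpt", ns)
  if (length(pts) == 0L) {
    return(data.frame(person_id = character(0),
                      t = as.POSIXct(character(0), tz = tz),
                      lat = numeric(0), lon = numeric(0),
                      accuracy_m = numeric(0)))
  }
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  tim <- xml2::xml_text(xml2::xml_find_first(pts, "./g:time", ns))
  t <- parse_iso8601(tim, tz = tz)
  if (anyNA(t) || anyNA(lat) || anyNA(lon)) {
    stop("unparseable trackpoint in ", path)
  }
  data.frame(person_id = person_id, t = t, lat = lat, lon = lon,
             accuracy_m = NA_real_, stringsAsFactors = FALSE)
}

#' Mobility date of a timestamp (03:00-anchored day)
#'
#' A mobility day runs from 03:00 local time to 02:59 the next calendar day,
#' so activity stretching past midnight is attributed to the day it started.
#' Implemented as the local calendar date of `t - 3 hours`.
#'
#' @param t POSIXct timestamp(s) with a timezone
#' @param tz timezone in which the wall clock is read (defaults to the
#'   timezone of `t`)
#' @return `Date` vector
#' @export
mobility_date_of <- function(t, tz = NULL) {
  stopifnot(inherits(t, "POSIXct"))
  if (is.null(tz)) tz <- attr(t, "tzone")
  if (is.null(tz) || !nzchar(tz[1])) tz <- "UTC"
  as.Date(t - 3 * 3600, tz = tz)
}

#' Split per-person fixes into mobility days
#'
#' Partitions a fix table by (person, mobility date). Every fix lands in
#' exactly one track day; dates with no fixes do not appear.
#'
#' @param fixes data.frame as returned by [read_gps_table]
#' @param tz study timezone for the 03:00 day boundary
#' @return list of track days; each element is a list with `person_id`,
#'   `mobility_date`, `fixes` (time-sorted data.frame), `coverage_hours`,
#'   `valid`
#' @export
split_days <- function(fixes, tz = "Europe/Berlin") {
  if (nrow(fixes) == 0L) return(list())
  fixes <- fixes[order(fixes$person_id, fixes$t), , drop = FALSE]
  md <- mobility_date_of(fixes$t, tz = tz)
  key <- paste(fixes$person_id, format(md), sep = "\r")
  idx <- split(seq_len(nrow(fixes)), key)
  # preserve person/date order rather than string order of the key
  idx <- idx[unique(key)]
  days <- lapply(idx, function(i) {
    f <- fixes[i, , drop = FALSE]
    rownames(f) <- NULL
    day <- list(person_id = f$person_id[1],
                mobility_date = mobility_date_of(f$t[1], tz = tz),
                fixes = f, tz = tz)
    day$coverage_hours <- coverage_hours(day)
    day$valid <- is_valid_day(day)
    class(day) <- "track_day"
    day
  })
  names(days) <- NULL
  days
}

#' @export
print.track_day <- function(x, ...) {
  cat(sprintf("<track_day %s %s: %d fixes, %d h coverage, %s>\n",
              x$person_id, format(x$mobility_date), nrow(x$fixes),
              x$coverage_hours, if (x$valid) "valid" else "invalid"))
  invisible(x)
}

#' Hours of a mobility day carrying GPS data
#'
#' Default rule: the number of distinct wall-clock hours of the day that
#' contain at least one fix (robust to differing fix rates). The
#' alternative `"cumulative"` rule sums recorded time instead, counting
#' inter-fix intervals no longer than `max_gap_min` and reporting full
#' covered hours (floored).
#'
#' @param day a `track_day`
#' @param rule `"distinct_hours"` (default) or `"cumulative"`
#' @param max_gap_min gap cap for the cumulative rule, minutes
#' @return integer number of hours, 0--24
#' @export
coverage_hours <- function(day, rule = c("distinct_hours", "cumulative"),
                           max_gap_min = 10) {
  rule <- match.arg(rule)
  f <- day$fixes
  if (is.null(f) || nrow(f) == 0L) return(0L)
  tz <- if (!is.null(day$tz)) day$tz else "UTC"
  if (rule == "distinct_hours") {
    hrs <- unique(format(f$t, "%H", tz = tz))
    return(length(hrs))
  }
  if (nrow(f) < 2L) return(0L)
  dt <- as.numeric(diff(f$t), units = "secs")
  covered <- sum(dt[dt <= max_gap_min * 60])
  as.integer(floor(covered / 3600))
}

#' Is a mobility day valid?
#'
#' A day enters the analyses when at least 8 hours of GPS data were
#' recorded.
#'
#' @param day a `track_day` (its `coverage_hours` is used if present)
#' @param min_hours validity threshold, default 8
#' @return logical
#' @export
is_valid_day <- function(day, min_hours = 8L) {
  ch <- if (!is.null(day$coverage_hours)) day$coverage_hours else coverage_hours(day)
  ch >= min_hours
}

#' Construct a home anchor
#'
#' @param person_id person identifier
#' @param lat,lon home coordinate (WGS84 degrees)
#' @param buffer_m radius of the home buffer in metres; a fix farther than
#'   this from home counts as out of home. Default 50.
#' @return a `home_anchor` list
#' @export
home_anchor <- function(person_id, lat, lon, buffer_m = 50) {
  stopifnot(buffer_m > 0)
  structure(list(person_id = as.character(person_id),
                 pos = geo_point(lat, lon), buffer_m = buffer_m),
            class = "home_anchor")
}

#' Read per-person home coordinates from CSV
#'
#' Columns: `person_id,lat,lon[,buffer_m]`.
#' @param path CSV path
#' @param buffer_m default buffer for rows without their own
#' @return named list of `home_anchor`, keyed by person id
#' @export
read_homes_table <- function(path, buffer_m = 50) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "lat", "lon")
  if (!all(need %in% names(raw))) {
    stop("homes CSV must have columns ", paste(need, collapse = ", "))
  }
  b <- if ("buffer_m" %in% names(raw)) raw$buffer_m else rep(buffer_m, nrow(raw))
  homes <- lapply(seq_len(nrow(raw)), function(i) {
    home_anchor(raw$person_id[i], raw$lat[i], raw$lon[i], b[i])
  })
  names(homes) <- as.character(raw$person_id)
  homes
}
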