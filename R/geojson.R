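# GeoJSON I/O for the environment layers. One FeatureCollection carries
# LineString features with a boolean `walkable` property (ways), Polygon
# features with a `green_category` property (green areas) and Point
# features with a `category` property (points of interest).

#' Read environment layers from GeoJSON
#'
#' @param path GeoJSON FeatureCollection file
#' @return list with `ways` (list of way segments), `green` (list of green
#'   polygons) and `pois` (data.frame `lat`, `lon`, `category`)
#' @export
read_env_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$features)) stop("not a GeoJSON FeatureCollection: ", path)
  ways <- list()
  green <- list()
  poi_rows <- list()
  for (ft in doc$features) {
    geom <- ft$geometry
    props <- ft$properties
    if (is.null(geom$type)) next
    if (geom$type == "LineString") {
      coords <- do.call(rbind, lapply(geom$coordinates, unlist))
      ways[[length(ways) + 1L]] <- list(
        polyline = data.frame(lat = coords[, 2], lon = coords[, 1]),
        walkable = isTRUE(props$walkable),
        way_id = if (!is.null(props$way_id)) props$way_id else length(ways) + 1L)
    } else if (geom$type == "Polygon") {
      ring <- do.call(rbind, lapply(geom$coordinates[[1]], unlist))
      green[[length(green) + 1L]] <- list(
        ring = data.frame(lat = ring[, 2], lon = ring[, 1]),
        category = if (!is.null(props$green_category)) props$green_category else "green")
    } else if (geom$type == "Point") {
      xy <- unlist(geom$coordinates)
      poi_rows[[length(poi_rows) + 1L]] <- data.frame(
        lat = xy[2], lon = xy[1],
        category = if (!is.null(props$category)) props$category else "unknown",
        stringsAsFactors = FALSE)
    }
  }
  pois <- if (length(poi_rows)) do.call(rbind, poi_rows) else
    data.frame(lat = numeric(0), lon = numeric(0), category = character(0))
  rownames(pois) <- NULL
  list(ways = ways, green = green, pois = pois)
}

#' Write environment layers to GeoJSON
#'
#' Emits the same dialect [read_env_geojson] reads, so layers round-trip.
#'
#' @param layers list with `ways`, `green`, `pois`
#' @param path output file
#' @export
write_env_geojson <- function(layers, path) {
  feat <- list()
  for (w in layers$ways) {
    feat[[length(feat) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(w$polyline)), function(i) {
                        c(w$polyline$lon[i], w$polyline$lat[i])
                      })),
      properties = list(walkable = isTRUE(w$walkable), way_id = w$way_id))
  }
  for (g in layers$green) {
    ring <- g$ring
    if (ring$lat[1] != ring$lat[nrow(ring)] || ring$lon[1] != ring$lon[nrow(ring)]) {
      ring <- rbind(ring, ring[1, ])
    }
    feat[[length(feat) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
                        c(ring$lon[i], ring$lat[i])
                      }))),
      properties = list(green_category = g$category))
  }
  if (!is.null(layers$pois) && nrow(layers$pois) > 0L) {
    for (i in seq_len(nrow(layers$pois))) {
      feat[[length(feat) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(layers$pois$lon[i], layers$pois$lat[i])),
        properties = list(category = layers$pois$category[i]))
    }
  }
  doc <- list(type = "FeatureCollection", features = feat)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
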