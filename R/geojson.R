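# Minimal GeoJSON (FeatureCollection of Polygons) input. Coordinates are
# lon/lat degrees and are projected on read; only the outer ring of each
# polygon is used (the sampling design needs outlines, not holes).

geojson_features <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$type) || g$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  g$features
}

geojson_outer_ring <- function(feature, ...) {
  geom <- feature$geometry
  ring <- switch(geom$type,
    Polygon = geom$coordinates[[1L]],
    MultiPolygon = {
      # largest part by vertex count
      parts <- lapply(geom$coordinates, function(p) p[[1L]])
      parts[[which.max(vapply(parts, length, 1L))]]
    },
    stop("unsupported geometry type: ", geom$type, call. = FALSE)
  )
  lon <- vapply(ring, function(v) as.numeric(v[[1L]]), 1)
  lat <- vapply(ring, function(v) as.numeric(v[[2L]]), 1)
  n <- length(lon)
  if (n > 1L && lon[1L] == lon[n] && lat[1L] == lat[n]) {
    lon <- lon[-n]
    lat <- lat[-n]
  }
  xy <- project_lambert(lon, lat, ...)
  cbind(xy$x, xy$y)
}

#' Read a landscape or species ranges from GeoJSON
#'
#' `read_landscape_geojson()` expects one Polygon/MultiPolygon feature per
#' ecoregion with properties `ecoregion` (id), `habitat` (`"forest"` or
#' `"open"`), and optionally logical `andes` and `atlantic`;
#' `read_ranges_geojson()` expects one feature per species with a `species`
#' property.  Coordinates are longitude/latitude degrees and are projected
#' to planar km on read (see [project_lambert()]); for multipolygons the
#' largest outer ring is used.
#'
#' @param path Path to a GeoJSON FeatureCollection.
#' @param ... Projection arguments passed to [project_lambert()].
#' @return A [new_landscape()] object, or a range tibble usable by
#'   [buffer_composition()] (with `area_sq_deg` precomputed).
#' @export
read_landscape_geojson <- function(path, ...) {
  feats <- geojson_features(path)
  eco <- dplyr::bind_rows(lapply(feats, function(f) {
    p <- f$properties
    tibble::tibble(
      ecoregion = p$ecoregion %||% stop("feature lacks an 'ecoregion' id"),
      habitat = p$habitat %||% stop("feature lacks a 'habitat' class"),
      andes = isTRUE(p$andes),
      atlantic = isTRUE(p$atlantic)
    )
  }))
  eco$polygon <- lapply(feats, geojson_outer_ring, ...)
  new_landscape(eco)
}

#' @rdname read_landscape_geojson
#' @export
read_ranges_geojson <- function(path, ...) {
  feats <- geojson_features(path)
  out <- dplyr::bind_rows(lapply(feats, function(f) {
    tibble::tibble(species = f$properties$species %||%
                     stop("feature lacks a 'species' property"))
  }))
  out$polygon <- lapply(feats, geojson_outer_ring, ...)
  out$area_sq_deg <- vapply(out$polygon, polygon_area_sq_deg, 1)
  out
}
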