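#' Create a polygon geometry
#'
#' A light planar polygon container: a list of rings, each an n-by-2 matrix of
#' vertices in metres (no repeated closing vertex). The first ring is the
#' outer boundary; any further rings are holes.
#'
#' @param rings A single n-by-2 matrix or a list of such matrices.
#' @param name Optional feature name carried into GeoJSON properties.
#' @return An object of class `geo_polygon`.
#' @export
geo_polygon <- function(rings, name = NULL) {
  if (is.matrix(rings)) rings <- list(rings)
  if (length(rings) == 0) abort("polygon needs at least one ring")
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2 || nrow(r) < 3) {
      abort("each polygon ring must be an n-by-2 matrix with n >= 3")
    }
    unname(r)
  })
  structure(list(rings = rings, name = name), class = "geo_polygon")
}

#' @export
print.geo_polygon <- function(x, ...) {
  cat("<geo_polygon>", length(x$rings), "ring(s),",
      nrow(x$rings[[1]]), "outer vertices\n")
  invisible(x)
}

close_ring <- function(r) rbind(r, r[1, , drop = FALSE])

feature_from_polygon <- function(p) {
  coords <- lapply(p$rings, function(r) {
    lapply(seq_len(nrow(r) + 1), function(i) {
      rr <- close_ring(r)
      c(rr[i, 1], rr[i, 2])
    })
  })
  props <- list(kind = "polygon")
  if (!is.null(p$name)) props$name <- p$name
  list(type = "Feature", properties = props,
       geometry = list(type = "Polygon", coordinates = coords))
}

feature_from_track <- function(fixes) {
  coords <- lapply(seq_len(nrow(fixes)), function(i) c(fixes$x[i], fixes$y[i]))
  list(
    type = "Feature",
    properties = list(
      kind = "trajectory",
      animal_id = fixes$animal_id[1],
      times = format(fixes$t, "%Y-%m-%dT%H:%M:%S"),
      behavior = fixes$behavior
    ),
    geometry = list(type = "LineString", coordinates = coords)
  )
}

#' Write trajectories and polygons to GeoJSON
#'
#' Serialises fix tables (as LineString features, one per animal, with
#' timestamps and behaviour in the feature properties) and [geo_polygon()]
#' objects (as Polygon features, holes supported) into a single GeoJSON
#' FeatureCollection. Coordinates are planar metres; the non-standard `crs`
#' member declares the local engineering frame so no consumer mistakes them
#' for longitude/latitude. [read_geojson()] reproduces the inputs exactly.
#'
#' @param x A fix tibble, a `geo_polygon`, or a list mixing the two.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(x, path) {
  if (inherits(x, "geo_polygon")) x <- list(x)
  if (is.data.frame(x)) x <- list(x)
  if (length(x) == 0) abort("no geometries to write")
  features <- list()
  for (obj in x) {
    if (inherits(obj, "geo_polygon")) {
      features <- c(features, list(feature_from_polygon(obj)))
    } else if (is.data.frame(obj)) {
      fixes <- as_fixes(obj)
      for (id in unique(fixes$animal_id)) {
        features <- c(features, list(
          feature_from_track(fixes[fixes$animal_id == id, ])
        ))
      }
    } else {
      abort("write_geojson() accepts fix tables and geo_polygon objects")
    }
  }
  doc <- list(
    type = "FeatureCollection",
    crs = list(type = "name",
               properties = list(name = "local-engineering-frame-metres")),
    features = features
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' Read geometries written by [write_geojson()]
#'
#' @param path Path to a GeoJSON file produced by [write_geojson()].
#' @return A list whose elements are fix tibbles (for trajectory features)
#'   and `geo_polygon` objects (for polygon features), in file order.
#' @export
read_geojson <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(doc$features, function(f) {
    geom <- f$geometry
    if (geom$type == "LineString") {
      xy <- do.call(rbind, lapply(geom$coordinates, unlist))
      tibble::tibble(
        animal_id = f$properties$animal_id,
        t = as.POSIXct(unlist(f$properties$times),
                       format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
        x = xy[, 1],
        y = xy[, 2],
        behavior = unlist(f$properties$behavior),
        source = "tracking"
      )
    } else if (geom$type == "Polygon") {
      rings <- lapply(geom$coordinates, function(ring) {
        m <- do.call(rbind, lapply(ring, unlist))
        m[-nrow(m), , drop = FALSE] # drop repeated closing vertex
      })
      geo_polygon(rings, name = f$properties$name)
    } else {
      abort(paste0("unsupported geometry type: ", geom$type))
    }
  })
}
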