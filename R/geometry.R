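#' Minimal planar polygon primitives
#'
#' The package works on an abstract planar grid in metres (inputs are assumed
#' co-registered; no CRS handling). Polygons are lists with elements `x` and
#' `y` (closed or open outer ring, counter-clockwise or clockwise) and an
#' optional `properties` list, matching what [read_geojson_polygons()]
#' returns. Holes are not supported; the habitat-layer inputs this package
#' consumes (reef, sandbank and photic-zone outlines) are simple rings.
#'
#' @name geometry
NULL

#' Exact polygon area (shoelace formula)
#'
#' @param poly list with numeric `x` and `y` of equal length (>= 3 distinct
#'   vertices); a repeated closing vertex is allowed.
#' @return area in squared input units (m^2 for metre coordinates).
#' @export
polygon_area <- function(poly) {
  x <- poly$x
  y <- poly$y
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  if (n < 3) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Points exactly on an edge may fall on either side; grid-cell centres are
#' generic with respect to input polygons in practice.
#'
#' @param px,py point coordinates.
#' @param poly polygon as in [polygon_area()].
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  x <- poly$x
  y <- poly$y
  n <- length(x)
  if (x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Read polygons from a GeoJSON file
#'
#' Supports FeatureCollection, Feature and bare Polygon/MultiPolygon
#' geometries; only outer rings are kept.
#'
#' @param path GeoJSON file.
#' @return list of polygons (`x`, `y`, `properties`).
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::read_json(path)
  feats <- switch(g$type,
                  FeatureCollection = g$features,
                  Feature = list(g),
                  Polygon = ,
                  MultiPolygon = list(list(geometry = g, properties = NULL)),
                  stop("unsupported GeoJSON type: ", g$type, call. = FALSE))
  out <- list()
  for (f in feats) {
    geom <- f$geometry
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    stop("unsupported geometry type: ", geom$type,
                         call. = FALSE))
    for (p in polys) {
      ring <- p[[1]]  # outer ring only
      xy <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
      out[[length(out) + 1L]] <- list(x = xy[, 1], y = xy[, 2],
                                      properties = f$properties)
    }
  }
  out
}

#' Write polygons to a GeoJSON file
#'
#' @param polys list of polygons (`x`, `y`, optional `properties`).
#' @param path output file.
#' @export
write_geojson_polygons <- function(polys, path) {
  feat <- lapply(polys, function(p) {
    x <- p$x; y <- p$y
    if (x[1] != x[length(x)] || y[1] != y[length(y)]) {
      x <- c(x, x[1]); y <- c(y, y[1])
    }
    ring <- mapply(function(a, b) list(a, b), x, y, SIMPLIFY = FALSE)
    list(type = "Feature",
         properties = if (is.null(p$properties)) structure(list(), names = character(0)) else p$properties,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
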