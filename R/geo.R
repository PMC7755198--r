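#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd ray-casting membership test for points against a polygon or
#' multipolygon given in longitude/latitude order. A point lying exactly on
#' a polygon edge or vertex counts as inside, matching the convention that a
#' record on the range boundary is within range. Holes are not supported;
#' the package's range polygons are unions of simple rings.
#'
#' @param longitude,latitude Numeric vectors of equal length.
#' @param polygon A two-column numeric matrix of `(longitude, latitude)`
#'   vertices, or a list of such matrices (multipolygon: inside any ring is
#'   inside). The closing vertex may be repeated or omitted.
#' @return Logical vector, one flag per point.
#' @examples
#' square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' point_in_polygon(c(0.5, 2), c(0.5, 0.5), square)
#' @export
point_in_polygon <- function(longitude, latitude, polygon) {
  rings <- as_rings(polygon)
  inside <- rep(FALSE, length(longitude))
  for (ring in rings) {
    inside <- inside | ring_contains(longitude, latitude, ring)
  }
  inside
}

# Normalize polygon input into a list of open rings (>= 3 distinct vertices).
as_rings <- function(polygon) {
  if (is.matrix(polygon)) polygon <- list(polygon)
  if (!is.list(polygon) || length(polygon) == 0) {
    stop("polygon must be a matrix or a non-empty list of matrices",
      call. = FALSE
    )
  }
  lapply(polygon, function(ring) {
    ring <- as.matrix(ring)
    if (ncol(ring) != 2 || any(!is.finite(ring))) {
      stop("polygon rings must be finite two-column matrices", call. = FALSE)
    }
    n <- nrow(ring)
    if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
    if (nrow(ring) < 3) {
      stop("degenerate polygon: fewer than 3 distinct vertices", call. = FALSE)
    }
    ring
  })
}

ring_contains <- function(x, y, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]
  ys <- ring[, 2]
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    # collinear with the edge and within its bounding box => on the boundary
    cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    on_edge <- on_edge | (
      cross == 0 &
        x >= pmin(x1, x2) & x <= pmax(x1, x2) &
        y >= pmin(y1, y2) & y <= pmax(y1, y2)
    )
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Default geographic scope: a generous Americas polygon
#'
#' The pipeline's scope filter discards records outside the species'
#' potential geographic range; the canonical example is a handful of European
#' records of captive birds. The default scope is a single generous rectangle
#' spanning the Americas (longitude -170 to -25, latitude -60 to 75); it is a
#' coarse screen for out-of-hemisphere records, not a range hypothesis, and
#' is fully overridable.
#'
#' @return A two-column `(longitude, latitude)` matrix.
#' @export
americas_polygon <- function() {
  cbind(
    longitude = c(-170, -25, -25, -170),
    latitude = c(-60, -60, 75, 75)
  )
}

#' The recognized-distribution polygon shipped with the package
#'
#' A deliberately coarse, synthetic stand-in for the most recognized range of
#' the American Flamingo: one ring covering the Caribbean basin, the Yucatan
#' Peninsula and the northern South American coast, and a second ring around
#' the Galapagos Islands. Suitable for classifying records as inside/outside
#' a recognized range in examples and tests; replace with a published range
#' polygon (GeoJSON) for real analyses.
#'
#' @return A list of `(longitude, latitude)` matrices (multipolygon).
#' @seealso [classify_against_range()], [read_polygon_geojson()]
#' @export
recognized_range_polygon <- function() {
  path <- system.file(
    "extdata", "recognized_range_synthetic.geojson",
    package = "flamingr"
  )
  read_polygon_geojson(path)
}

#' Read a polygon or multipolygon from a GeoJSON file
#'
#' Accepts a `Polygon` or `MultiPolygon` geometry, bare or wrapped in a
#' `Feature`/`FeatureCollection`. Only exterior rings are used.
#'
#' @param path Path to a GeoJSON file.
#' @return A list of `(longitude, latitude)` matrices.
#' @export
read_polygon_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  geom <- switch(gj$type %||% "",
    FeatureCollection = gj$features[[1]]$geometry,
    Feature = gj$geometry,
    gj
  )
  ring_to_matrix <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("longitude", "latitude")
    m
  }
  rings <- switch(geom$type %||% "",
    Polygon = list(ring_to_matrix(geom$coordinates[[1]])),
    MultiPolygon = lapply(geom$coordinates, function(poly) {
      ring_to_matrix(poly[[1]])
    }),
    stop("GeoJSON must contain a Polygon or MultiPolygon", call. = FALSE)
  )
  as_rings(rings)
}

#' Write classified records as a GeoJSON point collection
#'
#' Emits an RFC 7946 FeatureCollection with one point Feature per record and
#' the record's attributes (including any `inside_range` flag from
#' [classify_against_range()]) as Feature properties.
#'
#' @param records Occurrence-record tibble, optionally carrying an
#'   `inside_range` column.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_points_geojson <- function(records, path) {
  props <- c(
    "record_id", "country", "subnational", "locality_id", "date", "count",
    intersect("inside_range", names(records))
  )
  features <- purrr::pmap(
    records[c("longitude", "latitude", props)],
    function(longitude, latitude, date, count, ...) {
      list(
        type = "Feature",
        geometry = list(
          type = "Point",
          coordinates = c(longitude, latitude)
        ),
        properties = c(
          list(...),
          list(
            date = format(date, "%Y-%m-%d"),
            count = if (is.na(count)) "X" else count
          )
        )
      )
    }
  )
  fc <- list(type = "FeatureCollection", features = features)
  write_atomically(function(tmp) {
    jsonlite::write_json(fc, tmp, auto_unbox = TRUE, digits = NA)
  }, path)
}
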