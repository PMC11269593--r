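#' Simple planar geometry set
#'
#' Lightweight container for the vector features used in siting analysis:
#' a list of features, each `list(type, coords)` with `type` one of
#' `"Point"`, `"LineString"`, `"Polygon"` and `coords` an n x 2 coordinate
#' matrix (for polygons: the outer ring, not necessarily closed; holes are
#' unsupported). All coordinates are planar map units (metres).
#'
#' @param features list of `list(type, coords)` features.
#' @return An object of class `geom_set`.
#' @export
geom_set <- function(features = list()) {
  for (f in features) {
    stopifnot(is.list(f), f$type %in% c("Point", "LineString", "Polygon"),
              is.matrix(f$coords), ncol(f$coords) == 2)
  }
  structure(features, class = "geom_set")
}

#' @rdname geom_set
#' @param x,y coordinate scalars (Point) or vectors (LineString/Polygon vertices).
#' @export
geom_point <- function(x, y) list(type = "Point", coords = cbind(x, y))

#' @rdname geom_set
#' @export
geom_linestring <- function(x, y) list(type = "LineString", coords = cbind(x, y))

#' @rdname geom_set
#' @export
geom_polygon <- function(x, y) list(type = "Polygon", coords = cbind(x, y))

#' @export
print.geom_set <- function(x, ...) {
  types <- vapply(x, function(f) f$type, character(1))
  cat("geom_set:", length(x), "features (",
      paste(sprintf("%s:%d", names(table(types)), table(types)), collapse = ", "), ")\n")
  invisible(x)
}

# Minimum distance from each point (px, py) to segment (x1,y1)-(x2,y2).
# Vectorized over points; standard projection-onto-segment formula.
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Minimum distance from points to one feature's boundary (0 inside polygons).
dist_points_feature <- function(px, py, feature) {
  co <- feature$coords
  if (feature$type == "Point")
    return(sqrt((px - co[1, 1])^2 + (py - co[1, 2])^2))
  ring <- co
  if (feature$type == "Polygon" && !all(ring[1, ] == ring[nrow(ring), ]))
    ring <- rbind(ring, ring[1, , drop = FALSE])
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(ring) - 1)) {
    d <- pmin(d, dist_point_segment(px, py, ring[i, 1], ring[i, 2],
                                    ring[i + 1, 1], ring[i + 1, 2]))
  }
  if (feature$type == "Polygon")
    d[point_in_polygon(px, py, co)] <- 0
  d
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param px,py point coordinate vectors.
#' @param ring n x 2 matrix of polygon outer-ring vertices (closure optional).
#' @return Logical vector; points exactly on an edge may fall on either side.
#' @export
point_in_polygon <- function(px, py, ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ]))
    ring <- rbind(ring, ring[1, , drop = FALSE])
  n <- nrow(ring) - 1
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}
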