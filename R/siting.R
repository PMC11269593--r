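#' Reclassification table to ordinal 0-4 scores
#'
#' Bins are half-open `[from, to)`: a value exactly on an interior breakpoint
#' falls in the upper bin. Values below the table's first breakpoint take the
#' first score (plain table lookup); values in a gap between non-contiguous
#' bins, or at/above a finite final `to`, are a coverage error. Use `Inf` as
#' the final `to` for open-ended criteria.
#'
#' @param from,to numeric bin edges, ascending.
#' @param score ordinal scores in 0..4, one per bin (4 = most suitable).
#' @return data.frame reclass table.
#' @export
reclass_table <- function(from, to, score) {
  stopifnot(length(from) == length(to), length(score) == length(from),
            all(from < to), all(score %in% 0:4))
  if (is.unsorted(from, strictly = TRUE)) stop("bins must be in ascending order")
  data.frame(from = from, to = to, score = as.integer(score))
}

#' Reclassify a raster to ordinal suitability scores
#'
#' @param raster input [raster_layer()].
#' @param table a [reclass_table()].
#' @return Ordinal [raster_layer()] with values 0..4; NoData propagates.
#' @export
reclassify <- function(raster, table) {
  stopifnot(inherits(raster, "raster_layer"))
  v <- as.vector(raster$values)
  out <- rep(NA_real_, length(v))
  ok <- !is.na(v)
  idx <- findInterval(v[ok], table$from)          # 0 when below the first bin
  idx[idx == 0] <- 1L                             # below first breakpoint -> first score
  # coverage: value must fall inside its bin's [from, to)
  bad <- v[ok] >= table$to[idx]
  if (any(bad)) {
    offenders <- sort(unique(v[ok][bad]))
    stop("values outside reclass table coverage: ",
         paste(utils::head(offenders, 10), collapse = ", "))
  }
  out[ok] <- table$score[idx]
  raster_layer(raster$grid, matrix(out, raster$grid$n_rows, raster$grid$n_cols),
               kind = "ordinal")
}

#' Distance-to-nearest-feature raster
#'
#' Per cell, the Euclidean distance (map units) from the cell center to the
#' nearest geometry in the set; zero inside polygons and on lines.
#' Coordinates must be planar.
#'
#' @param geoms a non-empty [geom_set()].
#' @param grid target [grid_spec()].
#' @return Continuous [raster_layer()] of distances.
#' @export
distance_to_features <- function(geoms, grid) {
  stopifnot(inherits(geoms, "geom_set"), inherits(grid, "grid_spec"))
  if (!length(geoms)) stop("empty geometry set")
  ctr <- cell_centers(grid)
  d <- rep(Inf, nrow(ctr))
  for (f in geoms) d <- pmin(d, dist_points_feature(ctr$x, ctr$y, f))
  raster_layer(grid, matrix(d, grid$n_rows, grid$n_cols), kind = "continuous")
}

#' Build the siting exclusion mask
#'
#' A cell is excluded iff its center falls inside any military or protected
#' polygon, or lies within `airport_buffer_m` (inclusive) of any airport
#' point; union semantics across all exclusion features.
#'
#' @param grid target [grid_spec()].
#' @param military,protected `geom_set`s of polygons (or NULL).
#' @param airports `geom_set` of points (or NULL).
#' @param airport_buffer_m buffer radius around airports, metres.
#' @return Ordinal [raster_layer()] with 1 = excluded, 0 = open.
#' @export
build_exclusion_mask <- function(grid, military = NULL, protected = NULL,
                                 airports = NULL, airport_buffer_m = 1000) {
  ctr <- cell_centers(grid)
  excl <- rep(FALSE, nrow(ctr))
  for (set in list(military, protected)) {
    if (is.null(set)) next
    for (f in set) {
      if (f$type != "Polygon") stop("exclusion areas must be polygons")
      excl <- excl | point_in_polygon(ctr$x, ctr$y, f$coords)
    }
  }
  if (!is.null(airports)) {
    for (f in airports) {
      if (f$type != "Point") stop("airports must be points")
      d <- sqrt((ctr$x - f$coords[1, 1])^2 + (ctr$y - f$coords[1, 2])^2)
      excl <- excl | d <= airport_buffer_m
    }
  }
  raster_layer(grid, matrix(as.numeric(excl), grid$n_rows, grid$n_cols),
               kind = "ordinal")
}

#' Default siting criteria: weights and reclass tables
#'
#' The weights follow the published multi-criteria scheme: wind power class
#' 3, distance to roads 2, distance to transmission lines 2, land cover 2,
#' slope 2, population density 1. The breakpoint tables are documented,
#' config-overridable defaults in the style of the GIS siting literature
#' (wind power class maps classes 1..7 onto 0..4 with classes >= 5 most
#' suitable; gentler slopes, shorter infrastructure distances and sparser
#' population score higher; land-cover scores favour open grass/shrubland and
#' exclude urban and water). Distances are metres, slope percent, population
#' density persons per km^2.
#'
#' @param landcover_scores named or positional integer vector (0..4), one
#'   score per land-cover class id.
#' @return Named list of criteria: each has `weight` and `table`.
#' @export
default_criteria <- function(landcover_scores = c(4, 4, 3, 2, 0, 0)) {
  k <- length(landcover_scores)
  list(
    wind_power_class = list(weight = 3, table = reclass_table(
      from = c(1, 2, 3, 4, 5), to = c(2, 3, 4, 5, 8), score = c(0, 1, 2, 3, 4))),
    distance_to_roads = list(weight = 2, table = reclass_table(
      from = c(0, 2500, 5000, 10000, 20000),
      to = c(2500, 5000, 10000, 20000, Inf), score = c(4, 3, 2, 1, 0))),
    distance_to_transmission = list(weight = 2, table = reclass_table(
      from = c(0, 2500, 5000, 10000, 20000),
      to = c(2500, 5000, 10000, 20000, Inf), score = c(4, 3, 2, 1, 0))),
    landcover = list(weight = 2, table = reclass_table(
      from = seq_len(k), to = seq_len(k) + 1, score = landcover_scores)),
    slope = list(weight = 2, table = reclass_table(
      from = c(0, 5, 10, 15, 20), to = c(5, 10, 15, 20, Inf),
      score = c(4, 3, 2, 1, 0))),
    population_density = list(weight = 1, table = reclass_table(
      from = c(0, 10, 50, 150, 500), to = c(10, 50, 150, 500, Inf),
      score = c(4, 3, 2, 1, 0)))
  )
}

#' Weighted multi-criteria overlay
#'
#' Composite siting score per cell: the sum over criteria of weight times
#' ordinal score. With the default weights (3, 2, 2, 2, 2, 1) and scores 0-4
#' the composite ranges 0-48. Excluded cells and cells with any criterion
#' NoData become NoData (exclusions never masquerade as low suitability).
#'
#' @param score_rasters named list of aligned ordinal 0-4 rasters.
#' @param weights named numeric vector of positive integer weights; every
#'   name must be present in `score_rasters`.
#' @param exclusion optional exclusion mask raster (1 = excluded).
#' @return Ordinal [raster_layer()] of composite scores.
#' @export
weighted_overlay <- function(score_rasters, weights, exclusion = NULL) {
  missing_c <- setdiff(names(weights), names(score_rasters))
  if (length(missing_c))
    stop("missing criterion raster(s): ", paste(missing_c, collapse = ", "))
  stopifnot(all(weights > 0), all(weights == round(weights)))
  g <- score_rasters[[names(weights)[1]]]$grid
  total <- matrix(0, g$n_rows, g$n_cols)
  for (nm in names(weights)) {
    r <- score_rasters[[nm]]
    if (!grids_aligned(r$grid, g)) stop("criterion rasters are not aligned: ", nm)
    if (any(!(r$values %in% 0:4) & !is.na(r$values)))
      stop("criterion scores must be 0..4: ", nm)
    total <- total + weights[[nm]] * r$values   # NA propagates
  }
  if (!is.null(exclusion)) {
    if (!grids_aligned(exclusion$grid, g)) stop("exclusion mask is not aligned")
    total[exclusion$values == 1] <- NA_real_
  }
  raster_layer(g, total, kind = "ordinal")
}

#' Classify the siting score into low/moderate/high
#'
#' Integer score bands (inclusive): 0-16 low, 17-32 moderate, 33-48 high.
#'
#' @param score_map composite score raster from [weighted_overlay()].
#' @param bounds upper bounds of the low and moderate bands.
#' @return Ordinal [raster_layer()] with classes 1 (low), 2 (moderate),
#'   3 (high).
#' @export
classify_siting <- function(score_map, bounds = c(16, 32)) {
  v <- score_map$values
  if (any(v < 0 | v > 48, na.rm = TRUE)) stop("siting scores must lie in 0..48")
  cls <- ifelse(v <= bounds[1], 1, ifelse(v <= bounds[2], 2, 3))
  raster_layer(score_map$grid, cls, kind = "ordinal")
}

siting_class_labels <- c(`1` = "low", `2` = "moderate", `3` = "high")

#' Fraction of turbines below a siting-score cutoff
#'
#' Strict less-than comparison; the denominator is the number of turbines on
#' valid (non-NoData) cells, with NoData-cell turbines counted separately.
#'
#' @param turbines data.frame with `x`, `y`.
#' @param score_map composite score raster.
#' @param cutoff score cutoff.
#' @return list: `fraction`, `n_below`, `n_valid`, `n_nodata`.
#' @export
turbine_score_quantile <- function(turbines, score_map, cutoff) {
  s <- extract_at_points(score_map, turbines)$value
  valid <- !is.na(s)
  n_valid <- sum(valid)
  list(fraction = if (n_valid) sum(s[valid] < cutoff) / n_valid else 0,
       n_below = sum(s[valid] < cutoff), n_valid = n_valid,
       n_nodata = sum(!valid))
}

#' Build the full siting suitability products
#'
#' Convenience wrapper: computes distance rasters from road and transmission
#' geometries, reclassifies every criterion, applies the exclusion mask, and
#' returns the composite score and class maps.
#'
#' @param criteria_rasters named list with rasters `wind_power_class`,
#'   `slope`, `population_density`, `landcover` plus geom sets `roads`,
#'   `transmission_lines`, `military`, `protected`, `airports` (as produced
#'   by [generate_siting_criteria()]).
#' @param criteria criterion specs from [default_criteria()].
#' @param airport_buffer_m exclusion buffer around airports, metres.
#' @param class_bounds passed to [classify_siting()].
#' @return list: `score` (0-48 raster), `classes` (1/2/3 raster),
#'   `criterion_scores` (list of reclassified 0-4 rasters), `exclusion`.
#' @export
build_siting_map <- function(criteria_rasters, criteria = default_criteria(),
                             airport_buffer_m = 1000, class_bounds = c(16, 32)) {
  g <- criteria_rasters$wind_power_class$grid
  layers <- list(
    wind_power_class = criteria_rasters$wind_power_class,
    slope = criteria_rasters$slope,
    population_density = criteria_rasters$population_density,
    landcover = criteria_rasters$landcover,
    distance_to_roads = distance_to_features(criteria_rasters$roads, g),
    distance_to_transmission = distance_to_features(criteria_rasters$transmission_lines, g))
  scores <- lapply(names(criteria), function(nm)
    reclassify(layers[[nm]], criteria[[nm]]$table))
  names(scores) <- names(criteria)
  weights <- vapply(criteria, function(cr) cr$weight, numeric(1))
  excl <- build_exclusion_mask(g, military = criteria_rasters$military,
                               protected = criteria_rasters$protected,
                               airports = criteria_rasters$airports,
                               airport_buffer_m = airport_buffer_m)
  score <- weighted_overlay(scores, weights, exclusion = excl)
  list(score = score, classes = classify_siting(score, class_bounds),
       criterion_scores = scores, exclusion = excl)
}
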