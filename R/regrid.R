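#' Resample a raster onto a target grid
#'
#' Three methods cover the pipeline's needs: `nearest` assigns each target
#' cell the value of the source cell containing its center (any kind);
#' `bilinear` interpolates among the four nearest source cell centers
#' (continuous only); `mode_block` aggregates each target cell from the block
#' of source cells whose centers it covers by majority vote (categorical /
#' ordinal), ties broken toward the smallest class so aggregation is
#' deterministic. NoData propagates: a bilinear target cell is NoData if any
#' of its four neighbours is; a mode_block cell is NoData only when all source
#' cells in its block are.
#'
#' @param raster source [raster_layer()].
#' @param target target [grid_spec()] (same CRS as the source).
#' @param method `"nearest"`, `"mode_block"` or `"bilinear"`.
#' @return A [raster_layer()] on `target`, same kind as the source.
#' @export
regrid <- function(raster, target, method = c("nearest", "mode_block", "bilinear")) {
  method <- match.arg(method)
  stopifnot(inherits(raster, "raster_layer"), inherits(target, "grid_spec"))
  if (raster$grid$crs != target$crs)
    stop("source and target grids declare different CRS")
  if (method == "bilinear" && raster$kind != "continuous")
    stop("bilinear resampling is not valid for ", raster$kind, " rasters")
  if (method == "mode_block" && raster$kind == "continuous")
    stop("mode_block resampling is for categorical/ordinal rasters")
  if (grids_aligned(raster$grid, target)) return(raster)

  ctr <- cell_centers(target)
  vals <- switch(method,
    nearest = {
      rc <- cell_index(raster$grid, ctr$x, ctr$y)
      values_at_rc(raster, rc$row, rc$col)
    },
    bilinear = bilinear_sample(raster, ctr$x, ctr$y),
    mode_block = mode_block_sample(raster, target))
  raster_layer(target, matrix(vals, target$n_rows, target$n_cols), kind = raster$kind)
}

# Bilinear interpolation among the 4 nearest source cell centers; edge samples
# are clamped to the border row/column (degenerating to linear/nearest there).
bilinear_sample <- function(raster, x, y) {
  g <- raster$grid
  # fractional position in cell-center coordinates
  fc <- (x - g$x_min) / g$cell_size - 0.5
  fr <- (g$y_max - y) / g$cell_size - 0.5
  c0 <- pmin(pmax(floor(fc), 0), g$n_cols - 1)
  r0 <- pmin(pmax(floor(fr), 0), g$n_rows - 1)
  c1 <- pmin(c0 + 1, g$n_cols - 1)
  r1 <- pmin(r0 + 1, g$n_rows - 1)
  wc <- pmin(pmax(fc - c0, 0), 1)
  wr <- pmin(pmax(fr - r0, 0), 1)
  out <- x < g$x_min | x >= g$x_min + g$n_cols * g$cell_size |
    y > g$y_max | y <= g$y_max - g$n_rows * g$cell_size
  v00 <- raster$values[cbind(r0 + 1, c0 + 1)]
  v01 <- raster$values[cbind(r0 + 1, c1 + 1)]
  v10 <- raster$values[cbind(r1 + 1, c0 + 1)]
  v11 <- raster$values[cbind(r1 + 1, c1 + 1)]
  v <- (1 - wr) * ((1 - wc) * v00 + wc * v01) + wr * ((1 - wc) * v10 + wc * v11)
  v[out] <- NA_real_
  v
}

# Majority vote over the source cells whose centers fall inside each target
# cell; ties go to the smallest class value.
mode_block_sample <- function(raster, target) {
  src <- raster$grid
  ctr <- cell_centers(src)
  rc <- cell_index(target, ctr$x, ctr$y)
  v <- as.vector(raster$values)
  keep <- !is.na(rc$row) & !is.na(v)
  out <- rep(NA_real_, target$n_rows * target$n_cols)
  if (any(keep)) {
    idx <- (rc$col[keep] - 1L) * target$n_rows + rc$row[keep]
    by_cell <- split(v[keep], idx)
    modes <- vapply(by_cell, function(vals) {
      tab <- table(vals)
      classes <- as.numeric(names(tab))
      min(classes[tab == max(tab)])  # smallest class wins ties
    }, numeric(1))
    out[as.integer(names(by_cell))] <- modes
  }
  out
}

#' Extract raster values at point locations
#'
#' Each point is mapped to the cell whose half-open extent contains it (see
#' [grid_spec()] for the ownership convention). Points outside the grid are
#' flagged, not errors.
#'
#' @param raster a [raster_layer()].
#' @param points data.frame with `x`, `y` columns in the raster's CRS.
#' @return data.frame with columns `value` (NA when NoData or outside) and
#'   `outside` (logical, TRUE when the point falls off the grid).
#' @export
extract_at_points <- function(raster, points) {
  stopifnot(all(c("x", "y") %in% names(points)))
  rc <- cell_index(raster$grid, points$x, points$y)
  data.frame(value = values_at_rc(raster, rc$row, rc$col),
             outside = is.na(rc$row))
}
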