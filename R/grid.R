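#' Regular raster grid specification
#'
#' A `grid_spec` describes a regular, square-celled raster grid anchored at its
#' top-left corner. Cells are half-open: cell (row, col) owns the extent
#' `[x0, x0 + cell_size)` in x and `(y0 - cell_size, y0]` in y, where `x0`,
#' `y0` are the cell's left and top edges. Row/column indices are obtained by
#' flooring from the top-left origin, which removes any boundary ambiguity: a
#' point exactly on a vertical cell edge belongs to the right-hand cell, a
#' point on a horizontal edge to the cell above it.
#'
#' The CRS identifier is opaque metadata: no reprojection is ever performed,
#' all layers and points entering one analysis must share the same declared
#' CRS. Projected (planar) coordinates are assumed to be in metres.
#'
#' @param x_min x coordinate of the grid's left edge (map units).
#' @param y_max y coordinate of the grid's top edge (map units).
#' @param cell_size side length of the square cells (map units), > 0.
#' @param n_rows,n_cols grid dimensions, >= 1.
#' @param crs opaque CRS identifier string.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(x_min, y_max, cell_size, n_rows, n_cols, crs = "local-planar") {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1, cell_size > 0)
  stopifnot(n_rows >= 1, n_cols >= 1, n_rows == round(n_rows), n_cols == round(n_cols))
  structure(
    list(x_min = as.numeric(x_min), y_max = as.numeric(y_max),
         cell_size = as.numeric(cell_size),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         crs = as.character(crs)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g map units, origin (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_min, x$y_max, x$crs))
  invisible(x)
}

#' Test whether two grids are aligned
#'
#' Two grids are aligned iff every field (origin, cell size, dimensions, CRS)
#' is equal. All raster algebra in the package requires aligned grids.
#'
#' @param a,b `grid_spec` objects.
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  isTRUE(a$x_min == b$x_min && a$y_max == b$y_max &&
         a$cell_size == b$cell_size &&
         a$n_rows == b$n_rows && a$n_cols == b$n_cols && a$crs == b$crs)
}

#' Gridded raster layer
#'
#' Couples a [grid_spec()] with an `n_rows x n_cols` value matrix and a kind.
#' Missing cells are stored as `NA` (the on-disk NoData sentinel is handled by
#' [read_raster()]/[write_raster()]). NoData propagates through all raster
#' algebra: any operation on an `NA` cell yields `NA`.
#'
#' @param grid a `grid_spec`.
#' @param values numeric matrix with `dim == c(n_rows, n_cols)`; row 1 is the
#'   top (northernmost) row.
#' @param kind one of `"continuous"`, `"categorical"`, `"ordinal"`.
#'   Categorical/ordinal values must be integers where not `NA`.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values, kind = c("continuous", "categorical", "ordinal")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("values matrix does not match grid dimensions")
  if (kind != "continuous") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v)))
      stop("categorical/ordinal raster values must be integers")
  }
  structure(list(grid = grid, values = values, kind = kind), class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_layer (%s): %d x %d, %d NoData cells",
              x$kind, x$grid$n_rows, x$grid$n_cols, sum(is.na(x$values))))
  if (length(v)) cat(sprintf(", range [%g, %g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Map coordinates to cell indices
#'
#' Applies the half-open / floor ownership convention of [grid_spec()].
#' Points outside the grid get `NA` row/col.
#'
#' @param grid a `grid_spec`.
#' @param x,y coordinate vectors of equal length.
#' @return data.frame with integer columns `row`, `col` (`NA` when outside).
#' @export
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$x_min) / grid$cell_size) + 1
  row <- floor((grid$y_max - y) / grid$cell_size) + 1
  # top edge belongs to row 1; points exactly at y_max give row 1 not 0
  row[y == grid$y_max] <- 1L
  out <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    is.na(x) | is.na(y)
  col[out] <- NA_integer_
  row[out] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates
#'
#' @param grid a `grid_spec`.
#' @param row,col index vectors (default: all cells, column-major order).
#' @return data.frame with columns `x`, `y` (and `row`, `col`).
#' @export
cell_centers <- function(grid, row = NULL, col = NULL) {
  if (is.null(row)) {
    row <- rep(seq_len(grid$n_rows), times = grid$n_cols)
    col <- rep(seq_len(grid$n_cols), each = grid$n_rows)
  }
  data.frame(row = row, col = col,
             x = grid$x_min + (col - 0.5) * grid$cell_size,
             y = grid$y_max - (row - 0.5) * grid$cell_size)
}

#' Values at cell indices (NA-safe)
#' @keywords internal
values_at_rc <- function(raster, row, col) {
  v <- rep(NA_real_, length(row))
  ok <- !is.na(row) & !is.na(col)
  v[ok] <- raster$values[cbind(row[ok], col[ok])]
  v
}
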