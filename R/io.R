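#' Read a raster from an ESRI ASCII grid file
#'
#' Rasters are exchanged as single-band ESRI ASCII grids (`.asc`), a plain-text
#' format with a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of values, top row first.
#' Layer kind and CRS, which the format itself cannot carry, live in a JSON
#' sidecar written next to the grid (`<path>.json`); when the sidecar is
#' missing the layer is read as continuous with CRS `"unknown"`.
#'
#' Values are written with 17 significant digits so that write/read
#' round-trips reproduce doubles bit-exactly.
#'
#' @param path path to an `.asc` file.
#' @return A [raster_layer()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("not an ESRI ASCII grid (bad header): ", path)
    hdr[[tolower(parts[1])]] <- parts[2]
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header fields): ", path)
  n_cols <- as.integer(hdr$ncols); n_rows <- as.integer(hdr$nrows)
  cs <- as.numeric(hdr$cellsize)
  nodata <- as.numeric(hdr$nodata_value)
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != n_rows * n_cols)
    stop("raster body has ", length(vals), " values, expected ", n_rows * n_cols)
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  kind <- "continuous"; crs <- "unknown"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$kind)) kind <- meta$kind
    if (!is.null(meta$crs)) crs <- meta$crs
  }
  g <- grid_spec(x_min = as.numeric(hdr$xllcorner),
                 y_max = as.numeric(hdr$yllcorner) + n_rows * cs,
                 cell_size = cs, n_rows = n_rows, n_cols = n_cols, crs = crs)
  raster_layer(g, m, kind = kind)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' @param raster a [raster_layer()].
#' @param path output path (`.asc`); a `<path>.json` sidecar records kind and CRS.
#' @param nodata NoData sentinel written for `NA` cells.
#' @return Invisibly, `path`.
#' @rdname read_raster
#' @export
write_raster <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "raster_layer"))
  g <- raster$grid
  v <- raster$values
  if (any(v == nodata, na.rm = TRUE))
    stop("raster contains the NoData sentinel ", nodata, " as a real value")
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.17g", g$x_min),
           sprintf("yllcorner %.17g", g$y_max - g$n_rows * g$cell_size),
           sprintf("cellsize %.17g", g$cell_size),
           sprintf("NODATA_value %.17g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  jsonlite::write_json(list(kind = raster$kind, crs = g$crs),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a point table from CSV
#'
#' Point tables are plain data frames with an `id` column, planar or geographic
#' `x`/`y` coordinates, and arbitrary attribute columns. Column names in the
#' file are mapped through `columns`.
#'
#' @param path CSV file path.
#' @param columns named character vector mapping canonical names (`id`, `x`,
#'   `y`, ...) to file column names.
#' @return data.frame with at least `id`, `x`, `y`; ids unique, no missing
#'   coordinates.
#' @export
read_points_csv <- function(path, columns = c(id = "id", x = "x", y = "y")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(columns), names(df))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ", paste(missing_cols, collapse = ", "))
  for (canon in names(columns)) names(df)[names(df) == columns[[canon]]] <- canon
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  if (anyNA(df$x) || anyNA(df$y)) stop("point table has missing/unparseable coordinates")
  if (anyDuplicated(df$id)) stop("point table ids are not unique")
  df
}

#' Write a point table to CSV
#' @param points data.frame with `id`, `x`, `y` and attributes.
#' @param path output path.
#' @rdname read_points_csv
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read vector features from GeoJSON
#'
#' Supports Point, LineString and Polygon features (single outer ring, no
#' holes). Coordinates are taken as-is in the declared planar CRS.
#'
#' @param path GeoJSON file.
#' @return A `geom_set` (see [geom_set()]).
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection: ", path)
  feats <- lapply(gj$features, function(f) {
    geom <- f$geometry
    type <- geom$type
    co <- geom$coordinates
    coords <- switch(type,
      Point = matrix(unlist(co), ncol = 2, byrow = TRUE),
      LineString = do.call(rbind, lapply(co, function(p) unlist(p)[1:2])),
      Polygon = do.call(rbind, lapply(co[[1]], function(p) unlist(p)[1:2])),
      stop("unsupported GeoJSON geometry type: ", type))
    list(type = type, coords = coords)
  })
  geom_set(feats)
}

#' Write vector features to GeoJSON
#' @param geoms a `geom_set`.
#' @param path output path.
#' @rdname read_geojson
#' @export
write_geojson <- function(geoms, path) {
  stopifnot(inherits(geoms, "geom_set"))
  features <- lapply(geoms, function(f) {
    co <- switch(f$type,
      Point = as.list(f$coords[1, ]),
      LineString = lapply(seq_len(nrow(f$coords)), function(i) as.list(f$coords[i, ])),
      Polygon = list(lapply(seq_len(nrow(f$coords)), function(i) as.list(f$coords[i, ]))))
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = f$type, coordinates = co))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
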