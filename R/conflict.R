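#' Load and filter a turbine point table
#'
#' Industrial-scale turbines only: capacity strictly larger than
#' `min_capacity_kw` and rotor diameter strictly larger than `min_rotor_m`.
#' A record missing an attribute skips that filter (with a warning); dropped
#' counts are attached as the `"filter_log"` attribute.
#'
#' @param path_or_df CSV path or data.frame with `x`, `y` and optional
#'   `capacity_kw`, `rotor_m` columns.
#' @param min_capacity_kw,min_rotor_m strict lower bounds.
#' @param columns column mapping for CSV input (see [read_points_csv()]).
#' @return Filtered data.frame with attribute `filter_log`.
#' @export
load_turbines <- function(path_or_df, min_capacity_kw = 65, min_rotor_m = 30,
                          columns = c(id = "id", x = "x", y = "y")) {
  df <- if (is.character(path_or_df)) read_points_csv(path_or_df, columns) else path_or_df
  if (is.data.frame(df) && nrow(df) &&
      (anyNA(suppressWarnings(as.numeric(df$x))) ||
       anyNA(suppressWarnings(as.numeric(df$y)))))
    stop("unparseable turbine coordinates")
  n0 <- nrow(df)
  keep <- rep(TRUE, n0)
  for (spec in list(list(col = "capacity_kw", min = min_capacity_kw),
                    list(col = "rotor_m", min = min_rotor_m))) {
    if (!spec$col %in% names(df)) {
      warning("turbine table lacks ", spec$col, "; filter skipped")
      next
    }
    v <- df[[spec$col]]
    miss <- is.na(v)
    if (any(miss)) warning(sum(miss), " turbines missing ", spec$col, "; filter skipped for them")
    keep <- keep & (miss | v > spec$min)
  }
  out <- df[keep, , drop = FALSE]
  log <- list(input = n0, dropped = n0 - nrow(out), kept = nrow(out))
  message(sprintf("turbine filter: %d in, %d dropped, %d kept",
                  log$input, log$dropped, log$kept))
  attr(out, "filter_log") <- log
  out
}

impact_class_levels <- c("unlikely", "moderate", "high", "off_map")

#' Seasonal turbine impact table
#'
#' Assigns each turbine, per season, the habitat class of its containing cell
#' (unsuitable -> unlikely, low-to-moderate -> moderate, high -> high impact;
#' NoData or off-grid -> off_map) and tabulates counts and percentages of the
#' total turbine set. Per-season counts always sum to the turbine total and
#' percentages to 100.
#'
#' @param turbines data.frame with `x`, `y`.
#' @param habitat_maps named list (season -> [classify_habitat()] result).
#' @return data.frame with one row per season x impact class: `season`,
#'   `impact`, `count`, `percent`.
#' @export
turbine_impact_table <- function(turbines, habitat_maps) {
  n <- nrow(turbines)
  rows <- lapply(names(habitat_maps), function(season) {
    hm <- habitat_maps[[season]]
    cls <- extract_at_points(hm$raster, turbines)$value
    impact <- factor(ifelse(is.na(cls), "off_map",
                            impact_class_levels[cls + 1]),
                     levels = impact_class_levels)
    tab <- table(impact)
    data.frame(season = season, impact = names(tab),
               count = as.integer(tab),
               percent = if (n) 100 * as.integer(tab) / n else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

conflict_class_levels <- c(none = 0, minimum = 1, low = 2, high = 3)

#' Seasonal siting/habitat conflict map
#'
#' On cells classified high-suitability for siting, the conflict class
#' follows the seasonal habitat class: unsuitable habitat -> minimum
#' potential conflict, low-to-moderate habitat -> low, high habitat -> high.
#' All other cells are "none". Habitat maps on a coarser grid are regridded
#' to the siting grid by nearest neighbour when `regrid_habitat = TRUE`
#' (otherwise a grid mismatch is an error).
#'
#' @param siting_classes 1/2/3 raster from [classify_siting()].
#' @param habitat_map a `habitat_class_map`.
#' @param regrid_habitat allow nearest-neighbour regridding of the habitat map.
#' @return Ordinal [raster_layer()] with values 0 none, 1 minimum, 2 low,
#'   3 high.
#' @export
conflict_map <- function(siting_classes, habitat_map, regrid_habitat = TRUE) {
  hab <- habitat_map$raster
  if (!grids_aligned(hab$grid, siting_classes$grid)) {
    if (!regrid_habitat) stop("habitat and siting grids differ; set regrid_habitat = TRUE")
    hab <- regrid(hab, siting_classes$grid, method = "nearest")
  }
  s <- siting_classes$values
  h <- hab$values
  out <- matrix(0, nrow(s), ncol(s))
  out[is.na(s)] <- NA_real_
  hi <- !is.na(s) & s == 3
  out[hi] <- h[hi] + 1          # habitat 0/1/2 -> minimum/low/high
  out[hi & is.na(h)] <- NA_real_
  raster_layer(siting_classes$grid, out, kind = "ordinal")
}

#' Roost-buffer overlap report
#'
#' For each roost and for the union of all roost buffers: the number of
#' turbines within `buffer_km` (Euclidean point distance, <= inclusive) and
#' the area of high-siting-suitability cells whose centers lie within the
#' buffer. Buffer membership is computed directly from distances to roosts
#' rather than by discretizing buffer polygons, which is exact for point
#' roosts. The pooled row uses the buffer union, so nothing is double
#' counted.
#'
#' @param roosts data.frame with `x`, `y` (>= 1 row).
#' @param turbines data.frame with `x`, `y`.
#' @param siting_classes 1/2/3 raster from [classify_siting()].
#' @param buffer_km buffer radius, km (planar coordinates in metres).
#' @return list: `per_roost` (data.frame `roost`, `n_turbines`,
#'   `high_siting_km2`), `pooled` (same quantities for the buffer union),
#'   `buffer_km`.
#' @export
roost_buffer_overlap <- function(roosts, turbines, siting_classes, buffer_km = 100) {
  if (!nrow(roosts)) stop("empty roost set")
  buf_m <- buffer_km * 1000
  g <- siting_classes$grid
  ctr <- cell_centers(g)
  high <- !is.na(as.vector(siting_classes$values)) & as.vector(siting_classes$values) == 3
  cell_km2 <- (g$cell_size / 1000)^2
  t_in_any <- rep(FALSE, nrow(turbines))
  c_in_any <- rep(FALSE, nrow(ctr))
  per <- lapply(seq_len(nrow(roosts)), function(i) {
    dt <- sqrt((turbines$x - roosts$x[i])^2 + (turbines$y - roosts$y[i])^2)
    dc <- sqrt((ctr$x - roosts$x[i])^2 + (ctr$y - roosts$y[i])^2)
    t_in <- dt <= buf_m
    c_in <- dc <= buf_m
    t_in_any <<- t_in_any | t_in
    c_in_any <<- c_in_any | c_in
    data.frame(roost = if ("id" %in% names(roosts)) roosts$id[i] else i,
               n_turbines = sum(t_in),
               high_siting_km2 = sum(c_in & high) * cell_km2)
  })
  list(per_roost = do.call(rbind, per),
       pooled = list(n_turbines = sum(t_in_any),
                     high_siting_km2 = sum(c_in_any & high) * cell_km2),
       buffer_km = buffer_km)
}
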