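#!/usr/bin/env Rscript
# Stage 5: multi-criteria wind-turbine siting suitability.
#
# Reclassifies the six criteria to ordinal 0-4 scores, sums them under the
# weights (wind power class 3; roads, transmission, land cover, slope 2;
# population density 1) into the 0-48 composite, masks exclusions (military
# and protected polygons, 1-km airport buffers) as NoData, and bands the
# composite into low (0-16) / moderate (17-32) / high (33-48) siting classes.

suppressPackageStartupMessages(library(batwind))

scene <- "results/scene"
out <- "results/siting"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

crit <- list(
  wind_power_class = read_raster(file.path(scene, "siting_wind_power_class.asc")),
  slope = read_raster(file.path(scene, "siting_slope.asc")),
  population_density = read_raster(file.path(scene, "siting_population_density.asc")),
  landcover = read_raster(file.path(scene, "siting_landcover.asc")),
  roads = read_geojson(file.path(scene, "roads.geojson")),
  transmission_lines = read_geojson(file.path(scene, "transmission_lines.geojson")),
  military = read_geojson(file.path(scene, "military.geojson")),
  protected = read_geojson(file.path(scene, "protected.geojson")),
  airports = read_geojson(file.path(scene, "airports.geojson")))

maps <- build_siting_map(crit)
write_raster(maps$score, file.path(out, "siting_score.asc"))
write_raster(maps$classes, file.path(out, "siting_classes.asc"))

turb <- load_turbines("results/scene/turbines_raw.csv")
quant <- turbine_score_quantile(turb, maps$score, cutoff = 32)
write_points_csv(turb, file.path(out, "turbines_filtered.csv"))
jsonlite::write_json(quant, file.path(out, "turbine_score_quantile.json"),
                     auto_unbox = TRUE, digits = NA)

v <- maps$score$values
share <- table(factor(maps$classes$values, levels = 1:3)) / sum(!is.na(v))
cat(sprintf("siting score range %d-%d over %d valid cells (%d excluded as NoData)\n",
            min(v, na.rm = TRUE), max(v, na.rm = TRUE), sum(!is.na(v)), sum(is.na(v))))
cat(sprintf("class shares: %.1f%% low, %.1f%% moderate, %.1f%% high\n",
            100 * share[[1]], 100 * share[[2]], 100 * share[[3]]))
cat(sprintf("%.1f%% of %d on-map turbines sit below score 32 (%d on excluded cells)\n",
            100 * quant$fraction, quant$n_valid, quant$n_nodata))
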