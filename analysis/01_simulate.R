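#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study scene.
#
# Builds a seeded 100 x 100 km landscape (1-km habitat grid): four seasonal
# stacks of five continuous environmental fields plus a shared land cover, a
# known-truth suitability surface per season, raw museum-style occurrence
# records sampled from that truth, and the 300-m siting criteria (wind power
# class, slope, population density, land cover, roads, transmission lines,
# exclusion features). Everything downstream reads only the files written
# here.

suppressPackageStartupMessages(library(batwind))

seed <- 2026L
out <- "results/scene"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

grid <- grid_spec(0, 1e5, 1000, 100, 100, crs = "synthetic-planar-m")
cfg <- landscape_config(grid, seed = seed, autocorr_len = 5)
truth <- truth_model(c(temperature = 1.2, vapor = 1.0, wind = -0.8))

env <- generate_env_stack(cfg)
for (season in names(env)) {
  for (v in names(env[[season]])) {
    if (v == "landcover" && season != "spring") next  # shared across seasons
    write_raster(env[[season]][[v]],
                 file.path(out, sprintf("%s_%s.asc", v, season)))
  }
}
file.copy(file.path(out, "landcover_spring.asc"), file.path(out, "landcover.asc"),
          overwrite = TRUE)
file.copy(file.path(out, "landcover_spring.asc.json"),
          file.path(out, "landcover.asc.json"), overwrite = TRUE)

pres <- list()
for (i in seq_along(env)) {
  season <- names(env)[i]
  ts <- compute_truth_suitability(env[[season]], truth)
  write_raster(ts, file.path(out, sprintf("truth_suitability_%s.asc", season)))
  pres[[season]] <- sample_presences(ts, 200, seed = seed + 10 + i)
}
occ <- generate_occurrence_records(pres, seed = seed + 2)
write_points_csv(occ, file.path(out, "occurrences_raw.csv"))

sgrid <- grid_spec(0, 1e5, 300, ceiling(1e5 / 300), ceiling(1e5 / 300),
                   crs = "synthetic-planar-m")
crit <- generate_siting_criteria(cfg, seed = seed + 4, grid = sgrid)
for (v in c("wind_power_class", "slope", "population_density", "landcover", "elevation"))
  write_raster(crit[[v]], file.path(out, sprintf("siting_%s.asc", v)))
for (v in c("roads", "transmission_lines", "military", "protected", "airports"))
  write_geojson(crit[[v]], file.path(out, sprintf("%s.geojson", v)))

turb <- generate_turbines(500, crit$wind_power_class, bias = 1, seed = seed + 5)
write_points_csv(turb, file.path(out, "turbines_raw.csv"))
roosts <- generate_roosts(5, sgrid, seed = seed + 6)
write_points_csv(roosts, file.path(out, "roosts.csv"))

jsonlite::write_json(
  list(seed = seed, truth_coefficients = as.list(truth$coefficients),
       tau = truth$tau, grid_km = 100, habitat_cell_m = 1000,
       siting_cell_m = 300, n_presence_per_season = 200,
       n_turbines = 500, turbine_bias = 1, n_roosts = 5),
  file.path(out, "truth_manifest.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("scene written to %s: %d raw occurrence records, %d turbines, %d roosts\n",
            out, nrow(occ), nrow(turb), nrow(roosts)))
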