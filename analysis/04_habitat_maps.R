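#!/usr/bin/env Rscript
# Stage 4: three-class seasonal habitat maps from training-omission rates.
#
# For each season, the 10% and 50% training-omission thresholds are taken
# from the training-presence suitabilities written by stage 3, and the
# suitability raster is sliced into unsuitable (0), low-to-moderate (1) and
# high-suitability (2) habitat.

suppressPackageStartupMessages(library(batwind))

out <- "results/habitat"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

rows <- list()
for (season in c("spring", "summer", "fall", "winter")) {
  suit <- read_raster(sprintf("results/models/suitability_%s.asc", season))
  train <- utils::read.csv(sprintf("results/models/train_suitability_%s.csv", season))
  thr <- omission_thresholds(train$train_suitability, rates = c(0.10, 0.50))
  hm <- classify_habitat(suit, thr, season = season)
  write_raster(hm$raster, file.path(out, sprintf("habitat_classes_%s.asc", season)))
  jsonlite::write_json(list(season = season, t_low = thr$t_low,
                            t_high = thr$t_high, rates = thr$rates, m = thr$m),
                       file.path(out, sprintf("thresholds_%s.json", season)),
                       auto_unbox = TRUE, digits = NA)
  share <- table(factor(hm$raster$values, levels = 0:2)) / sum(!is.na(hm$raster$values))
  rows[[season]] <- data.frame(season = season, m = thr$m,
                               t_low = thr$t_low, t_high = thr$t_high,
                               pct_unsuitable = 100 * share[[1]],
                               pct_low_moderate = 100 * share[[2]],
                               pct_high = 100 * share[[3]])
  cat(sprintf("%s: thresholds %.4f / %.4f -> %0.1f%% unsuitable, %0.1f%% low-moderate, %0.1f%% high\n",
              season, thr$t_low, thr$t_high, 100 * share[[1]], 100 * share[[2]],
              100 * share[[3]]))
}
utils::write.csv(do.call(rbind, rows), file.path(out, "habitat_summary.csv"),
                 row.names = FALSE, quote = FALSE)
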