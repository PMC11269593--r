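test_that("environment stacks are pure functions of (config, seed)", {
  g <- grid_spec(0, 30000, 1000, 30, 30, crs = "s")
  cfg <- landscape_config(g, seed = 5, autocorr_len = 2)
  a <- generate_env_stack(cfg)
  b <- generate_env_stack(cfg)
  expect_identical(a, b)
  cfg2 <- landscape_config(g, seed = 6, autocorr_len = 2)
  expect_false(identical(generate_env_stack(cfg2), a))
})

test_that("unsmoothed fields hit the requested moments; land cover has k classes", {
  g <- grid_spec(0, 200000, 1000, 200, 200, crs = "s")
  cfg <- landscape_config(g, seed = 2, autocorr_len = 0, n_landcover_classes = 4)
  env <- generate_env_stack(cfg)
  tv <- env$spring$temperature$values
  spec <- cfg$continuous_specs[cfg$continuous_specs$name == "temperature", ]
  expect_lt(abs(stats::var(as.vector(tv)) - spec$sd^2) / spec$sd^2, 0.10)
  expect_lt(abs(mean(tv) - spec$mean), 0.5)
  expect_equal(sort(unique(as.vector(env$spring$landcover$values))), 1:4)
})

test_that("truth suitability follows the logistic link over standardized variables", {
  sc <- small_scene(n = 20)
  flat <- compute_truth_suitability(sc$env, truth_model(c(temperature = 0)))
  expect_true(all(flat$values == 0.5))

  mono <- compute_truth_suitability(sc$env, truth_model(c(temperature = 2)))
  o <- order(as.vector(sc$env$temperature$values))
  expect_true(all(diff(as.vector(mono$values)[o]) >= 0))

  # hand-computed single cell: linear + quadratic + product terms
  coefs <- c(temperature = 0.7, `vapor^2` = -0.4, `temperature:wind` = 0.25,
             `(Intercept)` = 0.1)
  suit <- compute_truth_suitability(sc$env, truth_model(coefs))
  std <- function(v, nm) {
    s <- default_continuous_specs()
    (v - s$mean[s$name == nm]) / s$sd[s$name == nm]
  }
  zt <- std(sc$env$temperature$values[3, 4], "temperature")
  zv <- std(sc$env$vapor$values[3, 4], "vapor")
  zw <- std(sc$env$wind$values[3, 4], "wind")
  expect_equal(suit$values[3, 4],
               plogis(0.1 + 0.7 * zt - 0.4 * zv^2 + 0.25 * zt * zw),
               tolerance = 1e-12)
})

test_that("presence sampling is truth-proportional, seeded, and cell-anchored", {
  g <- grid_spec(0, 20000, 1000, 20, 20, crs = "s")
  unif <- raster_layer(g, matrix(0.5, 20, 20), kind = "continuous")
  p <- sample_presences(unif, 4000, seed = 9)
  expect_identical(p, sample_presences(unif, 4000, seed = 9))
  # per-quadrant counts consistent with uniformity
  quad <- paste(p$x > 10000, p$y > 10000)
  expect_gt(chisq.test(table(quad), p = rep(0.25, 4))$p.value, 0.001)

  spike <- matrix(0, 20, 20); spike[7, 13] <- 1
  sp <- sample_presences(raster_layer(g, spike, kind = "continuous"), 50, seed = 1)
  expect_true(all(sp$x == cell_centers(g, 7, 13)$x & sp$y == cell_centers(g, 7, 13)$y))
})

test_that("empirical presence frequencies converge on truth probabilities", {
  sc <- small_scene(n = 20, seed = 3)
  v <- as.vector(sc$truth_suit$values)
  prob <- v / sum(v)
  counts <- numeric(length(v))
  for (rep in 1:10) {
    p <- sample_presences(sc$truth_suit, 10000, seed = 100 + rep)
    tab <- table(factor(p$cell, levels = seq_along(v)))
    counts <- counts + as.numeric(tab)
  }
  emp <- counts / sum(counts)
  expect_lt(max(abs(cumsum(sort(emp)) - cumsum(sort(prob)))), 0.01)
  expect_gt(cor(emp, prob), 0.99)
})

test_that("siting criteria have the declared structure and are seeded", {
  g <- grid_spec(0, 15000, 300, 50, 50, crs = "s")
  cfg <- landscape_config(grid_spec(0, 15000, 1000, 15, 15, crs = "s"), seed = 4)
  crit <- generate_siting_criteria(cfg, seed = 8, grid = g)
  expect_true(all(crit$wind_power_class$values %in% 1:7))
  expect_identical(crit, generate_siting_criteria(cfg, seed = 8, grid = g))
  expect_s3_class(crit$roads, "geom_set")
  expect_true(all(crit$slope$values >= 0))
  # flat elevation -> identically zero slope
  expect_true(all(slope_percent(matrix(500, 10, 10), 300) == 0))
})

test_that("turbine placement follows the wind-class bias", {
  g <- grid_spec(0, 40000, 1000, 40, 40, crs = "s")
  set.seed(2)
  wpc <- raster_layer(g, matrix(sample(1:7, 1600, replace = TRUE), 40, 40),
                      kind = "ordinal")
  expect_equal(nrow(generate_turbines(0, wpc)), 0)

  unbiased <- generate_turbines(1200, wpc, bias = 0, seed = 5)
  cls <- extract_at_points(wpc, unbiased)$value
  areal <- as.numeric(table(factor(wpc$values, levels = 1:7)))
  expect_gt(chisq.test(table(factor(cls, levels = 1:7)),
                       p = areal / sum(areal))$p.value, 0.001)

  biased <- generate_turbines(1200, wpc, bias = 3, seed = 5)
  cls_b <- extract_at_points(wpc, biased)$value
  top_frac_area <- mean(wpc$values == 7)
  expect_gt(mean(cls_b == 7), top_frac_area)
  # attributes drawn from the configured ranges
  expect_true(all(biased$capacity_kw > 65 & biased$rotor_m > 30))
})

test_that("occurrence record generator emulates a specimen download", {
  g <- grid_spec(0, 20000, 1000, 20, 20, crs = "s")
  unif <- raster_layer(g, matrix(0.5, 20, 20), kind = "continuous")
  pts <- lapply(c(spring = 1, summer = 2, fall = 3, winter = 4),
                function(s) sample_presences(unif, 100, seed = s))
  occ <- generate_occurrence_records(pts, seed = 3, contamination = 0.2,
                                     missing_month = 0.1)
  expect_equal(nrow(occ), 400)
  expect_true(any(occ$basis_of_record == "HumanObservation"))
  expect_true(any(is.na(occ$month)))
  ok <- !is.na(occ$month)
  expect_true(all(occ$month[ok] %in% 1:12))
  expect_true(all(occ$year >= 1970 & occ$year <= 2020))
  expect_identical(occ, generate_occurrence_records(pts, seed = 3,
                                                    contamination = 0.2,
                                                    missing_month = 0.1))
})
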