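test_that("reclassification uses half-open bins with explicit coverage errors", {
  tab <- reclass_table(from = c(0, 10, 20), to = c(10, 20, 30), score = c(4, 2, 0))
  r <- toy_raster(c(-5, 0, 10, 19.999, 20, NA), 2, 3)
  out <- reclassify(r, tab)
  # below first breakpoint -> first score; interior breakpoint -> upper bin
  expect_equal(as.vector(t(out$values)), c(4, 4, 2, 2, 0, NA))
  expect_error(reclassify(toy_raster(c(30, 0, 0, 0, 0, 0), 2, 3), tab),
               "outside reclass table coverage")
  expect_error(reclass_table(from = c(0, 5), to = c(5, 10), score = c(1, 7)))
})

test_that("distance rasters satisfy exact geometric oracles", {
  g <- grid_spec(0, 10000, 1000, 10, 10, crs = "m")
  expect_error(distance_to_features(geom_set(), g), "empty")

  # single point feature: 3-4-5 triangle from a cell center
  ctr <- cell_centers(g, 5, 5)  # (4500, 5500)
  pt <- geom_set(list(geom_point(ctr$x - 3000, ctr$y - 4000)))
  d <- distance_to_features(pt, g)
  expect_equal(d$values[5, 5], 5000)
  expect_true(all(d$values >= 0))

  # cell center exactly on a line -> 0
  line <- geom_set(list(geom_linestring(c(0, 10000), c(ctr$y, ctr$y))))
  dl <- distance_to_features(line, g)
  expect_equal(dl$values[5, 5], 0)
  # perpendicular distance from the next row's centers is one cell
  expect_equal(dl$values[4, 2], 1000)
})

test_that("exclusion mask uses union semantics and an inclusive airport buffer", {
  g <- grid_spec(0, 10000, 1000, 10, 10, crs = "m")
  expect_true(all(build_exclusion_mask(g)$values == 0))

  ctr <- cell_centers(g, 3, 3)
  apt_999 <- geom_set(list(geom_point(ctr$x + 999, ctr$y)))
  apt_1001 <- geom_set(list(geom_point(ctr$x + 1001, ctr$y)))
  expect_equal(build_exclusion_mask(g, airports = apt_999)$values[3, 3], 1)
  expect_equal(build_exclusion_mask(g, airports = apt_1001)$values[3, 3], 0)

  # overlapping military and protected polygons mask once (values stay 0/1)
  sq <- geom_set(list(geom_polygon(c(1000, 6000, 6000, 1000), c(1000, 1000, 6000, 6000))))
  m <- build_exclusion_mask(g, military = sq, protected = sq)
  expect_true(all(m$values %in% c(0, 1)))
  expect_equal(m$values[7, 4], 1)  # center (3500, 3500) inside
})

test_that("weighted overlay reproduces hand arithmetic and bounds", {
  g <- grid_spec(0, 2000, 1000, 2, 2, crs = "m")
  mk <- function(v) raster_layer(g, matrix(v, 2, 2), kind = "ordinal")
  weights <- c(wind_power_class = 3, distance_to_roads = 2,
               distance_to_transmission = 2, landcover = 2, slope = 2,
               population_density = 1)
  # all criteria at 4 -> the maximum composite score 48; all 0 -> 0
  all4 <- lapply(weights, function(w) mk(4))
  expect_true(all(weighted_overlay(all4, weights)$values == 48))
  all0 <- lapply(weights, function(w) mk(0))
  expect_true(all(weighted_overlay(all0, weights)$values == 0))
  # mixed scores: 3*4 + 2*3 + 2*2 + 2*1 + 2*0 + 1*4 = 28
  mixed <- Map(function(nm, s) mk(s), names(weights), c(4, 3, 2, 1, 0, 4))
  expect_true(all(weighted_overlay(mixed, weights)$values == 28))
  expect_error(weighted_overlay(mixed[-1], weights), "missing criterion")
})

test_that("weighted overlay matches brute force per cell; +1 shifts by the weight", {
  g <- grid_spec(0, 20000, 1000, 20, 50, crs = "m")
  weights <- c(a = 3, b = 2, c = 1)
  set.seed(13)
  layers <- lapply(weights, function(w) {
    v <- matrix(sample(0:4, 1000, replace = TRUE), 20, 50)
    v[sample(1000, 25)] <- NA
    raster_layer(g, v, kind = "ordinal")
  })
  score <- weighted_overlay(layers, weights)
  for (i in sample(1000, 1000)) {
    expected <- 3 * layers$a$values[i] + 2 * layers$b$values[i] + 1 * layers$c$values[i]
    expect_identical(score$values[i], expected)
  }
  # raising one criterion by a constant raises valid totals by its weight
  layers2 <- layers
  layers2$b$values <- pmin(layers2$b$values + 1, 4)
  bump <- layers2$b$values - layers$b$values  # 1 except where already 4
  score2 <- weighted_overlay(layers2, weights)
  ok <- !is.na(score$values) & bump == 1
  expect_true(all((score2$values - score$values)[ok] == weights["b"]))
})

test_that("exclusion produces NoData, never a low score", {
  g <- grid_spec(0, 3000, 1000, 3, 3, crs = "m")
  lay <- list(a = raster_layer(g, matrix(4, 3, 3), kind = "ordinal"))
  excl <- raster_layer(g, matrix(c(1, rep(0, 8)), 3, 3), kind = "ordinal")
  sc <- weighted_overlay(lay, c(a = 2), exclusion = excl)
  expect_true(is.na(sc$values[1, 1]))
  expect_true(all(sc$values[-1] == 8))
})

test_that("siting classes follow the inclusive 0-16/17-32/33-48 bands", {
  g <- grid_spec(0, 1000, 1000, 1, 8, crs = "m")
  sc <- raster_layer(g, matrix(c(0, 16, 17, 32, 33, 48, 20, NA), 1, 8),
                     kind = "ordinal")
  cls <- classify_siting(sc)
  expect_equal(as.vector(cls$values), c(1, 1, 2, 2, 3, 3, 2, NA))
  expect_error(classify_siting(raster_layer(g, matrix(c(49, rep(0, 7)), 1, 8),
                                            kind = "ordinal")), "0..48")
})

test_that("turbine score quantile counts strictly-below with NoData reported", {
  g <- grid_spec(0, 1000, 1000, 1, 6, crs = "m")
  sc <- raster_layer(g, matrix(c(10, 20, 31, 32, 40, NA), 1, 6), kind = "ordinal")
  turb <- cell_centers(g, rep(1, 6), 1:6)
  q <- turbine_score_quantile(turb, sc, 32)
  expect_equal(q$fraction, 3 / 5)  # NoData turbine excluded from the denominator
  expect_equal(q$n_nodata, 1)
  expect_equal(turbine_score_quantile(turb[1:5, ], sc, 0)$fraction, 0)
  all48 <- raster_layer(g, matrix(48, 1, 6), kind = "ordinal")
  expect_equal(turbine_score_quantile(turb, all48, 32)$fraction, 0)
})

test_that("the assembled siting map stays in range on a synthetic scene", {
  cfg <- landscape_config(grid_spec(0, 20000, 1000, 20, 20, crs = "m"), seed = 3)
  sgrid <- grid_spec(0, 20000, 500, 40, 40, crs = "m")
  crit <- generate_siting_criteria(cfg, seed = 9, grid = sgrid)
  maps <- build_siting_map(crit)
  v <- maps$score$values
  expect_true(all(v >= 0 & v <= 48, na.rm = TRUE))
  expect_true(all(maps$classes$values %in% c(1, 2, 3) | is.na(maps$classes$values)))
  # excluded cells are NoData in the score
  expect_true(all(is.na(v[maps$exclusion$values == 1])))
})
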