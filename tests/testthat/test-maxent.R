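test_that("LQP feature expansion has the right combinatorics, scaling and clamping", {
  df <- data.frame(a = c(0, 5, 10), b = c(-1, 0, 1), lc = c(2, 2, 7))
  fb <- build_features(df, c("a", "b"), "lc")
  # 2 linear + 2 quadratic + 1 product + 2 indicators
  expect_equal(ncol(fb$X), 7)
  expect_equal(colnames(fb$X),
               c("a", "a^2", "b", "b^2", "a:b", "lc=2", "lc=7"))
  expect_equal(fb$X[, "a"], c(0, 0.5, 1))
  expect_equal(fb$X[, "a^2"], c(0, 0.25, 1))
  expect_equal(fb$X[, "a:b"], c(0, 0.25, 1))
  # each row sums to 1 across the indicator block
  expect_equal(rowSums(fb$X[, c("lc=2", "lc=7")]), rep(1, 3))
  # evaluation outside training bounds is clamped
  X_new <- apply_features(fb$specs, data.frame(a = c(-100, 100), b = c(0, 0), lc = c(2, 9)))
  expect_equal(X_new[, "a"], c(0, 1))
  expect_equal(unname(X_new[2, c("lc=2", "lc=7")]), c(0, 0))
  # zero-variance variable dropped with a warning
  expect_warning(fb2 <- build_features(data.frame(a = c(1, 1, 1), b = 1:3),
                                       c("a", "b")), "zero-variance")
  expect_false("a" %in% colnames(fb2$X))
})

test_that("background sampling is uniform over valid cells, seeded, exhaustive", {
  g <- grid_spec(0, 10000, 1000, 10, 10, crs = "s")
  v <- matrix(rnorm(100), 10, 10); v[1:40] <- NA
  env <- list(z = raster_layer(g, v))
  expect_warning(bg <- sample_background(env, B = 100, seed = 1), "60 valid")
  expect_equal(nrow(bg), 60)
  bg2 <- sample_background(env, B = 30, seed = 5)
  expect_identical(bg2, sample_background(env, B = 30, seed = 5))
  expect_equal(anyDuplicated(bg2$cell), 0)
  allna <- list(z = raster_layer(g, matrix(NA_real_, 10, 10)))
  expect_error(sample_background(allna, 10, 1), "no valid")
})

test_that("no-signal data under strong regularization gives the null model", {
  set.seed(8)
  X_b <- cbind(runif(400), runif(400))
  colnames(X_b) <- c("u", "v")
  X_p <- X_b[sample(400, 80), , drop = FALSE]  # presences are background rows
  fit <- maxent_fit(X_p, X_b, reg_schema(rm = 50))
  expect_true(all(fit$lambda == 0))
  raw <- raw_at(fit, X_b)
  expect_equal(raw, rep(1 / 400, 400))
  expect_equal(logistic_at(fit, X_b), rep(0.5, 400))
  expect_equal(fit$H, log(400))
})

test_that("single-feature fit matches golden-section maximization of the gain", {
  m <- 100; B <- 400
  X_p <- matrix(1, m, 1)
  X_b <- matrix(rep(c(1, 0), each = B / 2), B, 1)
  # engineer beta = 0.05 through the schema: rm * epsilon_sd / sqrt(m)
  sch <- reg_schema(rm = 0.05 * sqrt(m) / 1e-4, epsilon_sd = 1e-4)
  fit <- maxent_fit(X_p, X_b, sch)
  expect_equal(unname(fit$beta), 0.05, tolerance = 1e-12)
  gold <- optimize(function(l) penalized_gain(l, X_p, X_b, fit$beta),
                   c(0, 20), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(fit$lambda), gold$maximum, tolerance = 1e-3)
  expect_lte(fit$kkt_residual, 1e-6)
})

test_that("two-feature fits match dense grid-search maximization within 1e-3", {
  set.seed(21)
  B <- 120; m <- 60
  X_b <- cbind(f1 = runif(B), f2 = runif(B)^2)
  idx <- sample(B, m, prob = exp(2 * X_b[, 1] - X_b[, 2]))
  X_p <- X_b[idx, , drop = FALSE]
  for (rm in c(0.5, 1.5)) {
    fit <- maxent_fit(X_p, X_b, reg_schema(rm = rm))
    grid_best <- function(center, span, step) {
      l1 <- seq(center[1] - span, center[1] + span, by = step)
      l2 <- seq(center[2] - span, center[2] + span, by = step)
      gr <- as.matrix(expand.grid(l1, l2))
      eta <- X_b %*% t(gr)
      lse <- apply(eta, 2, function(e) max(e) + log(sum(exp(e - max(e)))))
      J <- as.vector(colMeans(X_p %*% t(gr))) - lse + log(B) -
        abs(gr) %*% fit$beta
      gr[which.max(J), ]
    }
    coarse <- grid_best(c(0, 0), 4, 0.05)
    fine <- grid_best(coarse, 0.06, 0.001)
    expect_equal(unname(fit$lambda), unname(fine), tolerance = 2e-3)
    expect_lte(fit$kkt_residual, 1e-6)
  }
})

test_that("converged fits satisfy the KKT contract and background normalization", {
  for (seed in 1:3) {
    sc <- small_scene(n = 30, seed = seed)
    d <- scene_designs(sc, m = 80, B = 400, seed = seed)
    fit <- maxent_fit(d$X_p, d$X_b, reg_schema(rm = 1), specs = d$specs)
    expect_true(fit$converged)
    expect_lte(fit$kkt_residual, 1e-6)
    expect_equal(sum(raw_at(fit, d$X_b)), 1, tolerance = 1e-12)
    # independent KKT recheck from the returned coefficients
    w <- raw_at(fit, d$X_b)
    g <- colMeans(d$X_p) - as.vector(crossprod(d$X_b, w))
    res <- ifelse(fit$lambda == 0, pmax(abs(g) - fit$beta, 0),
                  abs(g - sign(fit$lambda) * fit$beta))
    expect_lte(max(res), 1e-6 + 1e-9)
  }
})

test_that("unpenalized training gain is non-increasing along the rm path", {
  sc <- small_scene(n = 30, seed = 12)
  d <- scene_designs(sc, m = 100, B = 500, seed = 2)
  gains <- vapply(c(0.5, 1, 2, 4), function(rm) {
    fit <- maxent_fit(d$X_p, d$X_b, reg_schema(rm = rm), specs = d$specs)
    penalized_gain(fit$lambda, d$X_p, d$X_b, rep(0, length(fit$lambda)))
  }, numeric(1))
  expect_true(all(diff(gains) <= 1e-8))
})

test_that("raw and logistic output match hand-computed scalars on a 3-cell toy", {
  lam <- c(0.8, -0.3)
  X_b <- rbind(c(0.2, 0.9), c(0.5, 0.1), c(1.0, 0.4))
  eta <- X_b %*% lam
  Z <- sum(exp(eta))
  raw <- exp(eta) / Z
  H <- -sum(raw * log(raw))
  fit <- structure(list(lambda = lam, log_Z = log(Z), H = H), class = "maxent_fit")
  expect_equal(raw_at(fit, X_b), as.vector(raw), tolerance = 1e-12)
  expect_equal(logistic_at(fit, X_b),
               as.vector(raw * exp(H) / (1 + raw * exp(H))), tolerance = 1e-12)
  # logistic strictly increasing in the linear predictor
  o <- order(eta)
  expect_true(all(diff(logistic_at(fit, X_b)[o]) > 0))
})

test_that("AICc follows the small-sample formula and its undefined flags", {
  fit2 <- structure(list(lambda = c(1, 2, 0), log_Z = 0), class = "maxent_fit")
  # craft designs so that lnL is exact: one extent row with raw = 1
  X_extent <- matrix(0, 1, 3)
  X_p <- matrix(0, 10, 3)
  a <- maxent_aicc(fit2, X_p, X_extent)  # lnL = 0, k = 2, m = 10
  expect_equal(a$aicc, 2 * 2 - 0 + 2 * 2 * 3 / (10 - 2 - 1))
  # the spec's worked example: k=2, m=10, lnL=-20
  aicc_formula <- function(k, m, lnL) 2 * k - 2 * lnL + 2 * k * (k + 1) / (m - k - 1)
  expect_equal(aicc_formula(2, 10, -20), 45.7142857142857, tolerance = 1e-10)
  # k = m - 1 -> undefined; k = 0 -> undefined
  fit9 <- structure(list(lambda = rep(1, 9), log_Z = 0), class = "maxent_fit")
  expect_false(maxent_aicc(fit9, matrix(0, 10, 9), matrix(0, 1, 9))$defined)
  fit0 <- structure(list(lambda = rep(0, 3), log_Z = 0), class = "maxent_fit")
  expect_false(maxent_aicc(fit0, X_p, X_extent)$defined)
  # fixed lnL, increasing k -> strictly increasing AICc
  expect_true(all(diff(vapply(1:7, aicc_formula, numeric(1), m = 10, lnL = -20)) > 0))
})

test_that("rm selection minimizes AICc with ties to the smaller multiplier", {
  expect_length(eval(formals(select_rm)$candidates), 10)
  sc <- small_scene(n = 30, seed = 5)
  d <- scene_designs(sc, m = 90, B = 400, seed = 3)
  sel <- select_rm(d$X_p, d$X_b, candidates = c(0.5, 1, 2), specs = d$specs)
  expect_equal(sel$best_rm, sel$table$rm[which.min(sel$table$aicc)])
  expect_equal(nrow(sel$table), 3)
  # explicit argmin with an independent AICc recomputation per candidate
  for (i in seq_len(nrow(sel$table))) {
    fit <- maxent_fit(d$X_p, d$X_b, reg_schema(rm = sel$table$rm[i]), specs = d$specs)
    a <- maxent_aicc(fit, d$X_p, d$X_b)
    expect_equal(a$aicc, sel$table$aicc[i], tolerance = 1e-8)
  }
  # tie rule: duplicated candidate values give the first (smallest)
  sel2 <- select_rm(d$X_p, d$X_b, candidates = c(1, 1), specs = d$specs)
  expect_equal(sel2$best_rm, 1)
})

test_that("AUC equals all-pairs enumeration, with ties counting one half", {
  expect_equal(auc_rank(c(5, 6), c(1, 2)), 1)
  expect_equal(auc_rank(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_error(auc_rank(numeric(0), 1), "non-empty")
  set.seed(77)
  for (i in 1:5) {
    p <- sample(1:10, 20, replace = TRUE)  # heavy ties
    b <- sample(1:10, 20, replace = TRUE)
    expect_equal(auc_rank(p, b), auc_all_pairs(p, b))
  }
  p <- rnorm(100); b <- rnorm(100)
  expect_equal(auc_rank(p, b), auc_all_pairs(p, b))
})

test_that("cross-validation is seeded, supports leave-one-out, separates a clean scene", {
  # a separable scene needs a *rare* high-suitability region: suitability ~1 on
  # ~4% of cells and ~0 elsewhere, so presences and background barely overlap
  sc <- small_scene(n = 40, seed = 9,
                    coefs = c(temperature = 8, `(Intercept)` = -14))
  d <- scene_designs(sc, m = 60, B = 400, seed = 11)
  cols <- c(env_vars, "landcover")
  cv <- cross_validate(d$pres[, cols], d$bg[, cols], env_vars, "landcover",
                       k = 5, seed = 3)
  expect_identical(cv, cross_validate(d$pres[, cols], d$bg[, cols], env_vars,
                                      "landcover", k = 5, seed = 3))
  expect_length(cv$fold_auc, 5)
  expect_gte(cv$mean, 0.95)

  loo <- cross_validate(d$pres[1:8, cols], d$bg[, cols], env_vars, "landcover",
                        k = 8, seed = 1)
  expect_length(loo$fold_auc, 8)
  expect_error(cross_validate(d$pres[1:3, cols], d$bg[, cols], env_vars,
                              "landcover", k = 5, seed = 1), "fewer presences")
})

test_that("response curves are flat for independent variables and well-formed", {
  sc <- small_scene(n = 40, seed = 14, coefs = c(temperature = 3))
  d <- scene_designs(sc, m = 150, B = 800, seed = 5)
  rc <- response_curves(d$pres, d$bg, continuous = c("temperature", "solar"),
                        categorical = "landcover", n_grid = 50)
  expect_true(all(rc$temperature$logistic > 0 & rc$temperature$logistic < 1))
  # solar does not drive the presence process -> near-flat around 0.5
  expect_lt(max(abs(rc$solar$logistic - 0.5)), 0.1)
  # temperature does -> visibly non-flat
  expect_gt(diff(range(rc$temperature$logistic)), 0.2)
  expect_equal(nrow(rc$landcover), length(unique(c(d$pres$landcover, d$bg$landcover))))
})

test_that("permutation contributions normalize to 100 and rank signal over noise", {
  sc <- small_scene(n = 40, seed = 16, coefs = c(temperature = 3))
  d <- scene_designs(sc, m = 150, B = 800, seed = 6)
  fit <- maxent_fit(d$X_p, d$X_b, reg_schema(rm = 1), specs = d$specs)
  eval_df <- rbind(d$pres[, c(env_vars, "landcover")], d$bg[, c(env_vars, "landcover")])
  labs <- c(rep(TRUE, nrow(d$pres)), rep(FALSE, nrow(d$bg)))
  vc <- variable_contribution(fit, eval_df, labs, n_perm = 5, seed = 2)
  expect_equal(sum(vc$percent), 100, tolerance = 1e-9)
  expect_equal(vc$variable[which.max(vc$percent)], "temperature")
  # pure-noise variables stay minor
  expect_lt(vc$percent[vc$variable == "solar"], 5)

  # single-variable model -> that variable carries 100%
  dfp <- data.frame(temperature = d$pres$temperature)
  dfb <- data.frame(temperature = d$bg$temperature)
  fb1 <- build_features(rbind(dfp, dfb), "temperature")
  fit1 <- maxent_fit(fb1$X[seq_len(nrow(dfp)), , drop = FALSE],
                     fb1$X[-seq_len(nrow(dfp)), , drop = FALSE],
                     reg_schema(rm = 1), specs = fb1$specs)
  vc1 <- variable_contribution(fit1, rbind(dfp, dfb),
                               c(rep(TRUE, nrow(dfp)), rep(FALSE, nrow(dfb))),
                               n_perm = 3, seed = 1)
  expect_equal(vc1$percent, 100)
})

test_that("collinearity screen flags strong pairs and survives degenerate input", {
  # duplicated layer: r = 1, flagged
  df <- data.frame(a = rnorm(50))
  df$b <- df$a
  scr <- collinearity_screen(df, threshold = 0.7)
  expect_equal(scr$r["a", "b"], 1)
  expect_equal(nrow(scr$flagged), 1)

  # 5-point toy checked against the explicit Pearson formula
  x <- c(1, 2, 3, 4, 5); y <- c(4, 1, 5, 0, 3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  scr2 <- collinearity_screen(data.frame(x = x, y = y), threshold = 0.99)
  expect_equal(scr2$r["x", "y"], r_hand, tolerance = 1e-12)

  # independent noise at large n stays below 0.05
  set.seed(4)
  noise <- as.data.frame(matrix(rnorm(10000 * 3), ncol = 3))
  scr3 <- collinearity_screen(noise)
  expect_lt(max(abs(scr3$r[upper.tri(scr3$r)])), 0.05)

  # zero variance -> NA correlations, flagged
  degen <- data.frame(a = rnorm(10), b = rep(1, 10))
  scr4 <- collinearity_screen(degen)
  expect_true(is.na(scr4$r["a", "b"]))
  expect_equal(nrow(scr4$flagged), 1)
})
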