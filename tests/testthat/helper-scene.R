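# Shared fixture builders. Everything is generated in code; nothing on disk.

# Tiny raster with explicit values (row-major input for readability).
toy_raster <- function(vals_by_row, n_rows, n_cols, cell_size = 1000,
                       kind = "continuous", x_min = 0, y_max = n_rows * cell_size,
                       crs = "toy") {
  g <- grid_spec(x_min, y_max, cell_size, n_rows, n_cols, crs = crs)
  raster_layer(g, matrix(vals_by_row, n_rows, n_cols, byrow = TRUE), kind = kind)
}

# Small seeded scene for model tests: one season's stack + truth surface.
small_scene <- function(n = 50, seed = 42, autocorr_len = 3,
                        coefs = c(temperature = 1.2, vapor = 1.0, wind = -0.8)) {
  g <- grid_spec(0, n * 1000, 1000, n, n, crs = "scene")
  cfg <- landscape_config(g, seed = seed, autocorr_len = autocorr_len)
  env <- generate_env_stack(cfg)$spring
  truth <- truth_model(coefs)
  list(grid = g, config = cfg, env = env,
       truth_suit = compute_truth_suitability(env, truth))
}

env_vars <- c("temperature", "solar", "vapor", "wind", "precip")

# Design matrices for presences/background sampled from a scene.
scene_designs <- function(scene, m = 120, B = 800, seed = 7,
                          categorical = "landcover") {
  pres_pts <- sample_presences(scene$truth_suit, m, seed = seed)
  bg <- sample_background(scene$env, B = B, seed = seed + 1)
  pres <- env_at_points(scene$env, pres_pts)
  cols <- c(env_vars, categorical)
  fb <- build_features(rbind(pres[, cols], bg[, cols]), env_vars, categorical)
  list(X_p = fb$X[seq_len(nrow(pres)), , drop = FALSE],
       X_b = fb$X[-seq_len(nrow(pres)), , drop = FALSE],
       specs = fb$specs, pres = pres, bg = bg)
}

# Independent brute-force AUC: enumerate all presence/background pairs.
auc_all_pairs <- function(p, b) {
  wins <- outer(p, b, ">") + 0.5 * outer(p, b, "==")
  mean(wins)
}

# Independent penalized-gain objective (for solver oracles).
penalized_gain <- function(lambda, X_p, X_b, beta) {
  eta <- as.vector(X_b %*% lambda)
  mean(X_p %*% lambda) - (max(eta) + log(sum(exp(eta - max(eta))))) +
    log(nrow(X_b)) - sum(beta * abs(lambda))
}
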