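#' Build an LQP design matrix with feature specifications
#'
#' Continuous variables are min-max scaled to [0, 1] using training bounds
#' computed over the supplied rows (presences and background together), then
#' expanded to linear, quadratic and pairwise-product features; a categorical
#' variable contributes one indicator feature per observed class. Evaluation
#' data outside the training bounds are clamped to the bounds before scaling
#' (see [apply_features()]).
#'
#' @param data data.frame of variable values at training locations
#'   (presences together with background).
#' @param continuous character vector of continuous variable names.
#' @param categorical character vector of categorical variable names.
#' @param kinds feature kinds to build, subset of
#'   `c("linear", "quadratic", "product")` (indicators are always built for
#'   categorical variables).
#' @return list with `X` (design matrix, one column per feature) and `specs`,
#'   a data.frame of feature specifications (`name`, `kind`, `var1`, `var2`,
#'   `train_min`, `train_max`, `level`). Zero-variance continuous variables
#'   are dropped with a warning.
#' @export
build_features <- function(data, continuous, categorical = character(0),
                           kinds = c("linear", "quadratic", "product")) {
  stopifnot(length(continuous) + length(categorical) >= 1)
  keep <- continuous
  for (v in continuous) {
    if (min(data[[v]]) == max(data[[v]])) {
      warning("dropping zero-variance variable: ", v)
      keep <- setdiff(keep, v)
    }
  }
  continuous <- keep
  specs <- list(); k <- 0
  add <- function(name, kind, var1, var2 = NA, tmin = NA, tmax = NA, level = NA) {
    k <<- k + 1
    specs[[k]] <<- data.frame(name = name, kind = kind, var1 = var1, var2 = var2,
                              train_min = tmin, train_max = tmax, level = level)
  }
  for (v in continuous) {
    tmin <- min(data[[v]]); tmax <- max(data[[v]])
    if ("linear" %in% kinds) add(v, "linear", v, tmin = tmin, tmax = tmax)
    if ("quadratic" %in% kinds) add(paste0(v, "^2"), "quadratic", v, tmin = tmin, tmax = tmax)
  }
  if ("product" %in% kinds && length(continuous) >= 2) {
    pairs <- utils::combn(continuous, 2)
    for (i in seq_len(ncol(pairs))) {
      v1 <- pairs[1, i]; v2 <- pairs[2, i]
      add(paste0(v1, ":", v2), "product", v1, v2)
    }
  }
  for (v in categorical) {
    for (lev in sort(unique(data[[v]])))
      add(paste0(v, "=", lev), "indicator", v, level = lev)
  }
  specs <- do.call(rbind, specs)
  # products reuse the per-variable bounds recorded on the linear rows
  bounds <- specs[specs$kind == "linear", c("var1", "train_min", "train_max")]
  feature_specs <- structure(list(specs = specs, bounds = bounds),
                             class = "feature_specs")
  list(X = apply_features(feature_specs, data), specs = feature_specs)
}

#' Evaluate feature specifications on new data
#'
#' Values outside the training bounds are clamped to the bounds before
#' min-max scaling, so every feature lies in [0, 1] everywhere.
#'
#' @param specs `feature_specs` from [build_features()].
#' @param data data.frame with the source variables.
#' @return Design matrix, one column per feature.
#' @export
apply_features <- function(specs, data) {
  stopifnot(inherits(specs, "feature_specs"))
  sp <- specs$specs
  scaled <- function(v) {
    i <- match(v, specs$bounds$var1)
    if (is.na(i)) stop("no training bounds for variable: ", v)
    lo <- specs$bounds$train_min[i]; hi <- specs$bounds$train_max[i]
    (pmin(pmax(data[[v]], lo), hi) - lo) / (hi - lo)
  }
  X <- matrix(0, nrow(data), nrow(sp), dimnames = list(NULL, sp$name))
  for (j in seq_len(nrow(sp))) {
    X[, j] <- switch(sp$kind[j],
      linear = scaled(sp$var1[j]),
      quadratic = scaled(sp$var1[j])^2,
      product = scaled(sp$var1[j]) * scaled(sp$var2[j]),
      indicator = as.numeric(data[[sp$var1[j]]] == sp$level[j]))
  }
  X
}

#' Sample background locations from an environment stack
#'
#' Uniform sample of valid (non-NoData in every layer) cells without
#' replacement; presences are not excluded. If fewer than `B` valid cells
#' exist, all of them are used with a warning.
#'
#' @param env named list of aligned [raster_layer()]s.
#' @param B number of background points (default 10000).
#' @param seed integer seed.
#' @return data.frame with `x`, `y`, `cell` and one column per variable.
#' @export
sample_background <- function(env, B = 10000, seed = 1L) {
  g <- env[[1]]$grid
  valid <- !is.na(env[[1]]$values)
  for (r in env) {
    if (!grids_aligned(r$grid, g)) stop("environment stack is not aligned")
    valid <- valid & !is.na(r$values)
  }
  ok <- which(valid)
  if (!length(ok)) stop("no valid (non-NoData) cells to sample background from")
  if (length(ok) < B) {
    warning("only ", length(ok), " valid cells; using all of them as background")
    cells <- ok
  } else {
    cells <- withr::with_seed(seed, sample(ok, B, replace = FALSE))
  }
  row <- ((cells - 1L) %% g$n_rows) + 1L
  col <- ((cells - 1L) %/% g$n_rows) + 1L
  ctr <- cell_centers(g, row, col)
  out <- data.frame(x = ctr$x, y = ctr$y, cell = cells)
  for (v in names(env)) out[[v]] <- env[[v]]$values[cbind(row, col)]
  out
}

#' Environmental values at point locations
#'
#' @param env named list of aligned rasters.
#' @param points data.frame with `x`, `y`.
#' @param drop_nodata drop points with NoData in any layer (with a message).
#' @return data.frame of `x`, `y` plus one column per variable.
#' @export
env_at_points <- function(env, points, drop_nodata = TRUE) {
  out <- points[, c("x", "y"), drop = FALSE]
  for (v in names(env)) out[[v]] <- extract_at_points(env[[v]], points)$value
  if (drop_nodata) {
    bad <- rowSums(is.na(out[, names(env), drop = FALSE])) > 0
    if (any(bad)) message("dropping ", sum(bad), " points on NoData cells")
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Regularization schema
#'
#' The per-feature L1 penalty is
#' `beta_j = rm * c_class(kind_j) * max(sd_j, epsilon_sd) / sqrt(m)`,
#' where `sd_j` is the feature's standard deviation over the `m` presences,
#' `rm` the tunable regularization multiplier, and `c_class` a base constant
#' per feature kind (all 1 by default).
#'
#' @param rm regularization multiplier, >= 0.
#' @param c_class named numeric vector of base constants per feature kind.
#' @param epsilon_sd floor on the feature sd entering the penalty.
#' @return An object of class `reg_schema`.
#' @export
reg_schema <- function(rm = 1,
                       c_class = c(linear = 1, quadratic = 1, product = 1, indicator = 1),
                       epsilon_sd = 1e-4) {
  stopifnot(rm >= 0, epsilon_sd > 0)
  structure(list(rm = rm, c_class = c_class, epsilon_sd = epsilon_sd),
            class = "reg_schema")
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a penalized maximum-entropy presence-background model
#'
#' Maximizes the regularized training gain
#' `J(lambda) = mean_i lambda.f(x_i) - log sum_b exp(lambda.f(z_b)) + log B
#'  - sum_j beta_j |lambda_j|`
#' by cyclic coordinate descent with a per-coordinate proximal Newton step and
#' objective-based backtracking. Convergence is declared on the KKT residual:
#' for `lambda_j = 0`, `|g_j| <= beta_j + tol`; otherwise
#' `|g_j - sign(lambda_j) beta_j| <= tol`, where `g_j` is the presence mean of
#' feature j minus its expectation under the fitted background distribution.
#' Non-convergence within `max_iter` sweeps returns `converged = FALSE` with
#' a warning, never silently.
#'
#' @param X_p presence design matrix (m x F), from [build_features()] /
#'   [apply_features()].
#' @param X_b background design matrix (B x F), same columns.
#' @param schema a [reg_schema()].
#' @param specs optional `feature_specs` carried along for prediction.
#' @param tol KKT tolerance.
#' @param max_iter maximum coordinate-descent sweeps.
#' @return An object of class `maxent_fit`: `lambda`, `beta`, `schema`,
#'   `specs`, `log_Z` (log normalizer over the training background), `H`
#'   (entropy of the fitted background distribution), `m`, `B`, `objective`
#'   (final penalized gain), `converged`, `kkt_residual`, `n_iter`.
#' @export
maxent_fit <- function(X_p, X_b, schema = reg_schema(), specs = NULL,
                       tol = 1e-6, max_iter = 2000) {
  stopifnot(is.matrix(X_p), is.matrix(X_b), ncol(X_p) == ncol(X_b))
  m <- nrow(X_p); B <- nrow(X_b); F_n <- ncol(X_p)
  if (m < 2) stop("need at least 2 presences")
  if (any(!is.finite(X_p)) || any(!is.finite(X_b))) stop("non-finite feature values")
  pbar <- colMeans(X_p)
  sd_p <- apply(X_p, 2, stats::sd)
  kind <- if (!is.null(specs)) specs$specs$kind else rep("linear", F_n)
  c_cl <- schema$c_class[kind]
  c_cl[is.na(c_cl)] <- 1
  beta <- schema$rm * c_cl * pmax(sd_p, schema$epsilon_sd) / sqrt(m)

  lambda <- rep(0, F_n)
  eta <- rep(0, B)                      # X_b %*% lambda
  objective <- function(lam, et) {
    sum(pbar * lam) - log_sum_exp(et) + log(B) - sum(beta * abs(lam))
  }
  obj <- objective(lambda, eta)
  kkt <- Inf; it <- 0
  while (it < max_iter) {
    it <- it + 1
    lse <- log_sum_exp(eta)
    w <- exp(eta - lse)                 # background distribution q
    for (j in seq_len(F_n)) {
      xj <- X_b[, j]
      qf <- sum(w * xj)
      g <- pbar[j] - qf
      h <- sum(w * xj * xj) - qf * qf
      if (h < 1e-10) h <- 1e-10
      z <- lambda[j] + g / h
      lnew <- sign(z) * max(abs(z) - beta[j] / h, 0)
      d <- lnew - lambda[j]
      if (d == 0) next
      # backtracking on the penalized objective
      for (step in 1:25) {
        cand_lambda <- lambda[j] + d
        cand_eta <- eta + d * xj
        cand_obj <- sum(pbar * lambda) - pbar[j] * lambda[j] + pbar[j] * cand_lambda -
          log_sum_exp(cand_eta) + log(B) -
          sum(beta * abs(lambda)) + beta[j] * abs(lambda[j]) - beta[j] * abs(cand_lambda)
        if (cand_obj >= obj - 1e-12) break
        d <- d / 2
      }
      if (cand_obj >= obj - 1e-12) {
        lambda[j] <- lambda[j] + d
        eta <- eta + d * xj
        obj <- cand_obj
        w <- exp(eta - log_sum_exp(eta))
      }
    }
    # KKT residual under the updated distribution
    lse <- log_sum_exp(eta)
    w <- exp(eta - lse)
    g_all <- pbar - as.vector(crossprod(X_b, w))
    res <- ifelse(lambda == 0,
                  pmax(abs(g_all) - beta, 0),
                  abs(g_all - sign(lambda) * beta))
    kkt <- max(res)
    if (kkt <= tol) break
  }
  converged <- kkt <= tol
  if (!converged)
    warning("maxent_fit did not converge in ", max_iter,
            " sweeps (KKT residual ", signif(kkt, 3), ")")
  lse <- log_sum_exp(eta)
  raw_b <- exp(eta - lse)
  H <- -sum(raw_b * ifelse(raw_b > 0, log(raw_b), 0))
  structure(list(lambda = stats::setNames(lambda, colnames(X_p)), beta = beta,
                 schema = schema, specs = specs, log_Z = lse, H = H,
                 m = m, B = B, objective = obj,
                 converged = converged, kkt_residual = kkt, n_iter = it),
            class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat(sprintf("maxent_fit: %d features (%d nonzero), m=%d presences, B=%d background\n",
              length(x$lambda), sum(x$lambda != 0), x$m, x$B))
  cat(sprintf("  rm=%g  gain=%.4f  H=%.4f  converged=%s (KKT %.2e, %d sweeps)\n",
              x$schema$rm, x$objective, x$H, x$converged, x$kkt_residual, x$n_iter))
  invisible(x)
}

#' Raw and logistic model output
#'
#' `raw_at()` returns the Gibbs density `exp(lambda.f(x) - log_Z)`, normalized
#' so it sums to 1 over the training background. `logistic_at()` rescales it
#' to a 0-1 suitability index at prevalence 0.5:
#' `logistic = raw e^H / (1 + raw e^H)`, where `H` is the entropy of the
#' fitted background distribution. With `lambda = 0` the raw density is
#' uniform (`1/B`) and the logistic output is exactly 0.5 everywhere.
#'
#' @param fit a [maxent_fit()].
#' @param X design rows built with the fit's feature specs (clamped).
#' @return Numeric vector of nonnegative weights (`raw_at`) or values in
#'   (0, 1) (`logistic_at`).
#' @export
raw_at <- function(fit, X) {
  stopifnot(inherits(fit, "maxent_fit"))
  exp(as.vector(X %*% fit$lambda) - fit$log_Z)
}

#' @rdname raw_at
#' @export
logistic_at <- function(fit, X) {
  r <- raw_at(fit, X) * exp(fit$H)
  r / (1 + r)
}

#' Predict a suitability raster from a fitted model
#'
#' @param fit a [maxent_fit()] carrying feature specs.
#' @param env named list of aligned rasters with the model's variables.
#' @param output `"logistic"` or `"raw"`.
#' @return Continuous [raster_layer()]; NoData where any variable is NoData.
#' @export
predict_raster <- function(fit, env, output = c("logistic", "raw")) {
  output <- match.arg(output)
  if (is.null(fit$specs)) stop("fit carries no feature specs; cannot predict")
  g <- env[[1]]$grid
  df <- data.frame(row.names = seq_len(g$n_rows * g$n_cols))
  for (v in names(env)) df[[v]] <- as.vector(env[[v]]$values)
  ok <- rowSums(is.na(df)) == 0
  vals <- rep(NA_real_, nrow(df))
  X <- apply_features(fit$specs, df[ok, , drop = FALSE])
  vals[ok] <- if (output == "logistic") logistic_at(fit, X) else raw_at(fit, X)
  raster_layer(g, matrix(vals, g$n_rows, g$n_cols), kind = "continuous")
}

#' Small-sample AIC of a fitted model
#'
#' Raw densities are renormalized to sum to 1 over the evaluation extent
#' (the training background by default); the log-likelihood is the sum of log
#' renormalized densities at the presences; `k` counts nonzero coefficients.
#' `AICc = 2k - 2 lnL + 2k(k+1)/(m - k - 1)`, undefined (flagged `NA`) when
#' `k = 0` or `k >= m - 1`.
#'
#' @param fit a [maxent_fit()].
#' @param X_p presence design rows.
#' @param X_extent design rows spanning the evaluation extent.
#' @return list: `aicc` (NA when undefined), `defined`, `k`, `lnL`, `m`.
#' @export
maxent_aicc <- function(fit, X_p, X_extent) {
  k <- sum(fit$lambda != 0)
  m <- nrow(X_p)
  raw_ext <- raw_at(fit, X_extent)
  p_pres <- raw_at(fit, X_p) / sum(raw_ext)
  lnL <- sum(log(p_pres))
  if (k == 0 || k >= m - 1)
    return(list(aicc = NA_real_, defined = FALSE, k = k, lnL = lnL, m = m))
  list(aicc = 2 * k - 2 * lnL + 2 * k * (k + 1) / (m - k - 1),
       defined = TRUE, k = k, lnL = lnL, m = m)
}

#' Select the regularization multiplier by AICc
#'
#' Fits one model per candidate multiplier and returns the candidate with the
#' lowest defined AICc; ties go to the smallest multiplier. The default
#' candidate grid covers 0.5 to 5 in steps of 0.5 (10 candidates).
#'
#' @param X_p,X_b presence / background design matrices.
#' @param candidates candidate multipliers.
#' @param specs optional `feature_specs` passed to each fit.
#' @param tol,max_iter solver controls, see [maxent_fit()].
#' @return list: `best_rm`, `table` (data.frame rm, k, lnL, aicc, converged),
#'   `fit` (the refitted winner).
#' @export
select_rm <- function(X_p, X_b, candidates = seq(0.5, 5, by = 0.5),
                      specs = NULL, tol = 1e-6, max_iter = 2000) {
  stopifnot(length(candidates) >= 1)
  rows <- lapply(candidates, function(rm) {
    fit <- maxent_fit(X_p, X_b, reg_schema(rm = rm), specs = specs,
                      tol = tol, max_iter = max_iter)
    a <- maxent_aicc(fit, X_p, X_b)
    data.frame(rm = rm, k = a$k, lnL = a$lnL, aicc = a$aicc,
               converged = fit$converged)
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$aicc)))
    stop("AICc undefined for every candidate regularization multiplier")
  best <- tab$rm[which.min(tab$aicc)]  # which.min skips NA; first = smallest rm on ties
  fit <- maxent_fit(X_p, X_b, reg_schema(rm = best), specs = specs,
                    tol = tol, max_iter = max_iter)
  list(best_rm = best, table = tab, fit = fit)
}

#' Rank-based AUC for presence vs background scores
#'
#' Mann-Whitney statistic: the probability that a random presence outscores a
#' random background point, ties counting one half. Equals all-pairs
#' enumeration exactly.
#'
#' @param presence_scores,background_scores non-empty numeric vectors.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(presence_scores, background_scores) {
  m <- length(presence_scores); B <- length(background_scores)
  if (m == 0 || B == 0) stop("both score sets must be non-empty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * B)
}

#' k-fold cross-validated test AUC
#'
#' Seeded random partition of the presences into k folds; for each fold the
#' model is fitted on the remaining presences (feature bounds recomputed from
#' the training presences plus the shared background) and test AUC is
#' computed on the held-out presences against the shared background.
#'
#' @param pres_df,bg_df data.frames of variable values at presences /
#'   background.
#' @param continuous,categorical variable names.
#' @param k number of folds.
#' @param seed integer seed.
#' @param schema a [reg_schema()].
#' @param tol,max_iter solver controls.
#' @return list: `fold_auc`, `mean`, `sd`, `folds` (fold id per presence).
#' @export
cross_validate <- function(pres_df, bg_df, continuous, categorical = character(0),
                           k = 5, seed = 1L, schema = reg_schema(),
                           tol = 1e-6, max_iter = 2000) {
  m <- nrow(pres_df)
  if (m < k) stop("fewer presences than folds")
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), m)))
  if (min(table(factor(folds, levels = seq_len(k)))) == 0)
    stop("a fold has zero presences")
  fold_auc <- vapply(seq_len(k), function(f) {
    tr <- pres_df[folds != f, , drop = FALSE]
    te <- pres_df[folds == f, , drop = FALSE]
    fb <- build_features(rbind(tr[, c(continuous, categorical), drop = FALSE],
                               bg_df[, c(continuous, categorical), drop = FALSE]),
                         continuous, categorical)
    X_tr <- fb$X[seq_len(nrow(tr)), , drop = FALSE]
    X_bg <- fb$X[-seq_len(nrow(tr)), , drop = FALSE]
    fit <- maxent_fit(X_tr, X_bg, schema, specs = fb$specs,
                      tol = tol, max_iter = max_iter)
    auc_rank(raw_at(fit, apply_features(fb$specs, te)),
             raw_at(fit, X_bg))
  }, numeric(1))
  list(fold_auc = fold_auc, mean = mean(fold_auc), sd = stats::sd(fold_auc),
       folds = folds)
}

#' Univariate response curves
#'
#' For each variable a univariate model is fitted (linear + quadratic
#' features for continuous variables, the indicator set for categorical
#' ones) at the default regularization multiplier, and its logistic output is
#' evaluated on an even grid spanning the variable's training range (one
#' value per observed class for categorical variables).
#'
#' @param pres_df,bg_df variable values at presences / background.
#' @param continuous,categorical variable names.
#' @param n_grid grid resolution for continuous curves.
#' @param rm regularization multiplier for the univariate fits.
#' @param tol,max_iter solver controls.
#' @return Named list of data.frames `value`, `logistic`.
#' @export
response_curves <- function(pres_df, bg_df, continuous, categorical = character(0),
                            n_grid = 100, rm = 1, tol = 1e-6, max_iter = 2000) {
  out <- list()
  for (v in continuous) {
    df_all <- rbind(pres_df[, v, drop = FALSE], bg_df[, v, drop = FALSE])
    fb <- build_features(df_all, continuous = v, kinds = c("linear", "quadratic"))
    X_p <- fb$X[seq_len(nrow(pres_df)), , drop = FALSE]
    X_b <- fb$X[-seq_len(nrow(pres_df)), , drop = FALSE]
    fit <- maxent_fit(X_p, X_b, reg_schema(rm = rm), specs = fb$specs,
                      tol = tol, max_iter = max_iter)
    grid_vals <- seq(min(df_all[[v]]), max(df_all[[v]]), length.out = n_grid)
    nd <- stats::setNames(data.frame(grid_vals), v)
    out[[v]] <- data.frame(value = grid_vals,
                           logistic = logistic_at(fit, apply_features(fb$specs, nd)))
  }
  for (v in categorical) {
    df_all <- rbind(pres_df[, v, drop = FALSE], bg_df[, v, drop = FALSE])
    fb <- build_features(df_all, continuous = character(0), categorical = v)
    X_p <- fb$X[seq_len(nrow(pres_df)), , drop = FALSE]
    X_b <- fb$X[-seq_len(nrow(pres_df)), , drop = FALSE]
    fit <- maxent_fit(X_p, X_b, reg_schema(rm = rm), specs = fb$specs,
                      tol = tol, max_iter = max_iter)
    levs <- sort(unique(df_all[[v]]))
    nd <- stats::setNames(data.frame(levs), v)
    out[[v]] <- data.frame(value = levs,
                           logistic = logistic_at(fit, apply_features(fb$specs, nd)))
  }
  out
}

#' Permutation variable contributions
#'
#' For each source variable, its values are permuted (jointly across all
#' features derived from it) over the evaluation rows `n_perm` times and the
#' average drop in training AUC is recorded; negative drops are floored at 0
#' and the drops normalized to percentages summing to 100. When every drop is
#' zero the percentages are uniform, with a warning.
#'
#' @param fit a [maxent_fit()] carrying feature specs.
#' @param eval_df variable values at evaluation rows (presences + background).
#' @param is_presence logical vector over `eval_df` rows.
#' @param n_perm permutations per variable.
#' @param seed integer seed.
#' @return data.frame `variable`, `drop`, `percent` (summing to 100).
#' @export
variable_contribution <- function(fit, eval_df, is_presence, n_perm = 10, seed = 1L) {
  stopifnot(inherits(fit, "maxent_fit"), !is.null(fit$specs))
  sp <- fit$specs$specs
  vars <- unique(c(sp$var1, sp$var2[!is.na(sp$var2)]))
  base_scores <- raw_at(fit, apply_features(fit$specs, eval_df))
  base_auc <- auc_rank(base_scores[is_presence], base_scores[!is_presence])
  drops <- withr::with_seed(seed, vapply(vars, function(v) {
    mean(vapply(seq_len(n_perm), function(p) {
      df <- eval_df
      df[[v]] <- df[[v]][sample(nrow(df))]
      s <- raw_at(fit, apply_features(fit$specs, df))
      base_auc - auc_rank(s[is_presence], s[!is_presence])
    }, numeric(1)))
  }, numeric(1)))
  drops <- pmax(drops, 0)
  if (all(drops == 0)) {
    warning("all permutation drops are zero; reporting uniform contributions")
    pct <- rep(100 / length(vars), length(vars))
  } else {
    pct <- 100 * drops / sum(drops)
  }
  data.frame(variable = vars, drop = unname(drops), percent = unname(pct))
}

#' Pairwise collinearity screen
#'
#' Pearson correlations between continuous variables at the sample locations;
#' pairs at or above the threshold are flagged but nothing is dropped
#' automatically (strongly correlated pairs may legitimately be retained).
#' Zero-variance variables yield `NA` correlations, flagged.
#'
#' @param sample_df data.frame of continuous variable values at >= 3 sample
#'   locations.
#' @param threshold absolute correlation flag threshold.
#' @return list: `r` (correlation matrix), `flagged` (data.frame `var1`,
#'   `var2`, `r`), `threshold`.
#' @export
collinearity_screen <- function(sample_df, threshold = 0.7) {
  if (nrow(sample_df) < 3) stop("need at least 3 sample locations")
  r <- suppressWarnings(stats::cor(sample_df))
  pairs <- which(upper.tri(r) & (abs(r) >= threshold | is.na(r)), arr.ind = TRUE)
  flagged <- data.frame(var1 = rownames(r)[pairs[, 1]],
                        var2 = colnames(r)[pairs[, 2]],
                        r = r[pairs])
  list(r = r, flagged = flagged, threshold = threshold)
}
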