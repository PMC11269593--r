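#' Synthetic landscape configuration
#'
#' Describes the seeded synthetic scene used to exercise the whole pipeline
#' with known truth: spatially autocorrelated continuous environmental fields
#' (seasonal means of temperature, solar radiation, water vapour pressure,
#' wind speed and precipitation), a k-class land-cover field, and the siting
#' criteria. Continuous fields are white noise smoothed with a uniform disk
#' kernel of radius `autocorr_len` cells and affinely rescaled to the
#' requested mean/sd; land cover is a smoothed field quantile-sliced into
#' `n_landcover_classes` classes and, as in real land-cover products, held
#' constant across seasons. Seasonal fields mix an independent per-season
#' component with a shared component (`shared_weight`) so seasonal layers
#' differ but correlate, as real climate layers do.
#'
#' Default moments are round figures typical of the species' semi-arid range:
#' temperature 15 +/- 8 degC, solar radiation 15000 +/- 3000 kJ m-2 day-1,
#' vapour pressure 1.2 +/- 0.4 kPa, wind speed 4 +/- 1.5 m s-1, seasonal
#' precipitation 60 +/- 30 mm.
#'
#' @param grid [grid_spec()] for the habitat-model layers.
#' @param seed integer master seed; all generators are pure functions of
#'   (config, seed).
#' @param autocorr_len smoothing radius in cells (>= 0).
#' @param continuous_specs data.frame with columns `name`, `mean`, `sd`.
#' @param n_landcover_classes number of land-cover classes (>= 2).
#' @param n_seasons number of seasons (default 4).
#' @param shared_weight in [0,1]; share of variance common to all seasons.
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(grid, seed = 1L, autocorr_len = 5,
                             continuous_specs = default_continuous_specs(),
                             n_landcover_classes = 6L, n_seasons = 4L,
                             shared_weight = 0.5) {
  stopifnot(inherits(grid, "grid_spec"), autocorr_len >= 0,
            n_landcover_classes >= 2, n_seasons >= 1,
            shared_weight >= 0, shared_weight <= 1,
            all(c("name", "mean", "sd") %in% names(continuous_specs)))
  structure(list(grid = grid, seed = as.integer(seed),
                 autocorr_len = autocorr_len,
                 continuous_specs = continuous_specs,
                 n_landcover_classes = as.integer(n_landcover_classes),
                 n_seasons = as.integer(n_seasons),
                 shared_weight = shared_weight),
            class = "landscape_config")
}

#' @rdname landscape_config
#' @export
default_continuous_specs <- function() {
  data.frame(name = c("temperature", "solar", "vapor", "wind", "precip"),
             mean = c(15, 15000, 1.2, 4, 60),
             sd = c(8, 3000, 0.4, 1.5, 30))
}

season_names <- function(n = 4L) c("spring", "summer", "fall", "winter")[seq_len(n)]

# Uniform-disk smoothing of a matrix (zero-padded edges, renormalized by the
# actual kernel overlap so edge cells are unbiased). radius in cells.
smooth_field <- function(m, radius) {
  if (radius <= 0) return(m)
  r <- ceiling(radius)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc); norm <- matrix(0, nr, nc)
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    sr <- max(1, 1 - di):min(nr, nr - di)   # source rows shifted by di
    tr <- sr + di
    sc <- max(1, 1 - dj):min(nc, nc - dj)
    tc <- sc + dj
    acc[tr, tc] <- acc[tr, tc] + m[sr, sc]
    norm[tr, tc] <- norm[tr, tc] + 1
  }
  acc / norm
}

# Smoothed standard-normalish field on the config grid (mean 0, sd 1 exactly).
standard_field <- function(grid, radius) {
  f <- smooth_field(matrix(stats::rnorm(grid$n_rows * grid$n_cols),
                           grid$n_rows, grid$n_cols), radius)
  (f - mean(f)) / stats::sd(f)
}

#' Generate the seasonal environmental stack
#'
#' @param config a [landscape_config()].
#' @return Named list (one element per season) of environment stacks; each
#'   stack is a named list of [raster_layer()]s: the continuous variables from
#'   `continuous_specs` plus a categorical `landcover` layer shared across
#'   seasons. Same config (including seed) gives bit-identical output.
#' @export
generate_env_stack <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  g <- config$grid
  withr::with_seed(config$seed, {
    lc_field <- standard_field(g, config$autocorr_len)
    qs <- stats::quantile(lc_field, probs = seq(0, 1, length.out = config$n_landcover_classes + 1))
    lc <- matrix(findInterval(lc_field, qs[-c(1, length(qs))]) + 1, g$n_rows, g$n_cols)
    landcover <- raster_layer(g, lc, kind = "categorical")

    shared <- lapply(config$continuous_specs$name, function(v)
      standard_field(g, config$autocorr_len))
    names(shared) <- config$continuous_specs$name
    w <- config$shared_weight
    seasons <- lapply(season_names(config$n_seasons), function(season) {
      stack <- lapply(seq_len(nrow(config$continuous_specs)), function(i) {
        spec <- config$continuous_specs[i, ]
        own <- standard_field(g, config$autocorr_len)
        f <- sqrt(w) * shared[[spec$name]] + sqrt(1 - w) * own
        f <- (f - mean(f)) / stats::sd(f) * spec$sd + spec$mean
        raster_layer(g, f, kind = "continuous")
      })
      names(stack) <- config$continuous_specs$name
      stack$landcover <- landcover
      stack
    })
    names(seasons) <- season_names(config$n_seasons)
    seasons
  })
}

#' Known-truth suitability model
#'
#' Named coefficients over linear (`"temperature"`), quadratic
#' (`"temperature^2"`) and pairwise product (`"temperature:vapor"`) terms of
#' the continuous variables, plus an optional `"(Intercept)"`. Coefficients
#' apply to standardized variables `(v - mean) / sd` using the moments in
#' `standardize` (defaults to [default_continuous_specs()]), so order-1
#' coefficients are comparable across variables with different units.
#'
#' @param coefficients named numeric vector; all finite.
#' @param tau prevalence constant in (0,1); the logistic intercept offset
#'   `qlogis(tau)` (default 0.5, i.e. no offset).
#' @param standardize data.frame `name`, `mean`, `sd` used to standardize.
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(coefficients, tau = 0.5,
                        standardize = default_continuous_specs()) {
  stopifnot(is.numeric(coefficients), all(is.finite(coefficients)),
            !is.null(names(coefficients)), tau > 0, tau < 1)
  structure(list(coefficients = coefficients, tau = tau, standardize = standardize),
            class = "truth_model")
}

#' Cellwise truth suitability surface
#'
#' Logistic transform of the truth linear predictor over the environment
#' stack's standardized variables: with all coefficients zero the surface is
#' constant at `tau`. NoData propagates.
#'
#' @param env one season's environment stack (named list of rasters).
#' @param truth a [truth_model()].
#' @return Continuous [raster_layer()] with values in (0, 1).
#' @export
compute_truth_suitability <- function(env, truth) {
  stopifnot(inherits(truth, "truth_model"))
  g <- env[[1]]$grid
  for (r in env) if (!grids_aligned(r$grid, g)) stop("environment stack is not aligned")
  std <- function(v) {
    i <- match(v, truth$standardize$name)
    if (is.na(i)) stop("no standardization moments for variable: ", v)
    (env[[v]]$values - truth$standardize$mean[i]) / truth$standardize$sd[i]
  }
  lp <- matrix(stats::qlogis(truth$tau), g$n_rows, g$n_cols)
  for (term in names(truth$coefficients)) {
    b <- truth$coefficients[[term]]
    val <- if (term == "(Intercept)") {
      matrix(1, g$n_rows, g$n_cols)
    } else if (grepl("\\^2$", term)) {
      std(sub("\\^2$", "", term))^2
    } else if (grepl(":", term, fixed = TRUE)) {
      vars <- strsplit(term, ":", fixed = TRUE)[[1]]
      std(vars[1]) * std(vars[2])
    } else {
      std(term)
    }
    lp <- lp + b * val
  }
  raster_layer(g, stats::plogis(lp), kind = "continuous")
}

#' Sample presence points from a truth surface
#'
#' Cells are sampled with replacement with probability proportional to the
#' truth suitability value; points sit at cell centers. Exact duplicates are
#' retained deliberately so downstream occurrence cleaning has work to do.
#'
#' @param truth continuous [raster_layer()] with values in [0, 1].
#' @param n number of points.
#' @param seed integer seed.
#' @return data.frame point table: `id`, `x`, `y`, `cell` (linear cell index).
#' @export
sample_presences <- function(truth, n, seed) {
  stopifnot(inherits(truth, "raster_layer"))
  v <- as.vector(truth$values)
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("truth surface must lie in [0, 1]")
  ok <- which(!is.na(v) & v > 0)
  if (!length(ok)) stop("truth surface has no positive cells to sample")
  cells <- withr::with_seed(seed,
    ok[sample.int(length(ok), size = n, replace = TRUE, prob = v[ok])])
  g <- truth$grid
  row <- ((cells - 1L) %% g$n_rows) + 1L
  col <- ((cells - 1L) %/% g$n_rows) + 1L
  ctr <- cell_centers(g, row, col)
  data.frame(id = seq_len(n), x = ctr$x, y = ctr$y, cell = cells)
}

#' Generate synthetic siting criteria
#'
#' Produces the raster criteria and vector features of the turbine-siting
#' analysis on the given grid: an ordinal 1-7 wind power class (quantile
#' slices of a smooth field), slope in percent (gradient magnitude of a
#' synthetic elevation field), a right-skewed population density surface, a
#' categorical land cover, seeded random road and transmission-line
#' polylines, and exclusion features (military/protected polygons, airport
#' points).
#'
#' @param config a [landscape_config()]; generation happens on `grid` unless
#'   a different (typically finer) `grid` argument is supplied.
#' @param seed integer seed (independent of the environment-stack seed).
#' @param grid optional [grid_spec()] overriding `config$grid`.
#' @param n_roads,n_lines,n_polygons,n_airports feature counts.
#' @return Named list: rasters `wind_power_class`, `slope`,
#'   `population_density`, `landcover`; `geom_set`s `roads`,
#'   `transmission_lines`, `military`, `protected`, `airports`; and
#'   `elevation` (the field slope was derived from).
#' @export
generate_siting_criteria <- function(config, seed, grid = NULL,
                                     n_roads = 6L, n_lines = 4L,
                                     n_polygons = 3L, n_airports = 3L) {
  stopifnot(inherits(config, "landscape_config"))
  g <- if (is.null(grid)) config$grid else grid
  withr::with_seed(seed, {
    wf <- standard_field(g, config$autocorr_len)
    qs <- stats::quantile(wf, probs = seq(0, 1, length.out = 8))
    wpc <- matrix(findInterval(wf, qs[-c(1, 8)]) + 1, g$n_rows, g$n_cols)

    # elevation in metres; slope (%) from central-difference gradient
    elev <- standard_field(g, config$autocorr_len * 2) * 400 + 1200
    slope <- slope_percent(elev, g$cell_size)

    pop <- exp(standard_field(g, config$autocorr_len) * 1.5 + 2)  # ~people/km2

    lc_field <- standard_field(g, config$autocorr_len)
    qlc <- stats::quantile(lc_field,
                           probs = seq(0, 1, length.out = config$n_landcover_classes + 1))
    lc <- matrix(findInterval(lc_field, qlc[-c(1, length(qlc))]) + 1,
                 g$n_rows, g$n_cols)

    extent_w <- g$n_cols * g$cell_size
    extent_h <- g$n_rows * g$cell_size
    random_polyline <- function() {
      n_seg <- sample(3:6, 1)
      x <- g$x_min + cumsum(c(stats::runif(1), stats::runif(n_seg, -0.3, 0.3))) * extent_w
      y <- g$y_max - cumsum(c(stats::runif(1), stats::runif(n_seg, -0.3, 0.3))) * extent_h
      geom_linestring(x, y)
    }
    random_blob <- function() {
      cx <- g$x_min + stats::runif(1, 0.1, 0.9) * extent_w
      cy <- g$y_max - stats::runif(1, 0.1, 0.9) * extent_h
      ang <- seq(0, 2 * pi, length.out = 9)[-9]
      rad <- stats::runif(8, 0.03, 0.10) * min(extent_w, extent_h)
      geom_polygon(cx + rad * cos(ang), cy + rad * sin(ang))
    }
    random_points <- function(n) {
      geom_set(lapply(seq_len(n), function(i)
        geom_point(g$x_min + stats::runif(1) * extent_w,
                   g$y_max - stats::runif(1) * extent_h)))
    }

    list(wind_power_class = raster_layer(g, wpc, kind = "ordinal"),
         slope = raster_layer(g, slope, kind = "continuous"),
         population_density = raster_layer(g, pop, kind = "continuous"),
         landcover = raster_layer(g, lc, kind = "categorical"),
         elevation = raster_layer(g, elev, kind = "continuous"),
         roads = geom_set(lapply(seq_len(n_roads), function(i) random_polyline())),
         transmission_lines = geom_set(lapply(seq_len(n_lines), function(i) random_polyline())),
         military = geom_set(lapply(seq_len(n_polygons), function(i) random_blob())),
         protected = geom_set(lapply(seq_len(n_polygons), function(i) random_blob())),
         airports = random_points(n_airports))
  })
}

#' Slope in percent from an elevation matrix
#'
#' Central differences in the interior, one-sided at the borders; slope is
#' `100 * sqrt((dz/dx)^2 + (dz/dy)^2)`. A flat field gives identically zero.
#'
#' @param elev elevation matrix (map units, metres).
#' @param cell_size cell side length (metres).
#' @return Matrix of slope percentages.
#' @export
slope_percent <- function(elev, cell_size) {
  nr <- nrow(elev); nc <- ncol(elev)
  right <- elev[, c(2:nc, nc)]; left <- elev[, c(1, 1:(nc - 1))]
  down <- elev[c(2:nr, nr), ]; up <- elev[c(1, 1:(nr - 1)), ]
  dzdx <-(right - left) / (cell_size * matrix(rep(c(1, rep(2, nc - 2), 1), each = nr), nr, nc))
  dzdy <- (down - up) / (cell_size * matrix(rep(c(1, rep(2, nr - 2), 1), nc), nr, nc))
  100 * sqrt(dzdx^2 + dzdy^2)
}

#' Generate turbine and roost point tables
#'
#' Turbine cells are sampled (with replacement) with probability proportional
#' to `exp(bias * wind_power_class)`, emulating preferential siting in windy
#' cells; `bias = 0` gives uniform placement. Capacity and rotor diameter are
#' drawn uniformly from the configured ranges.
#'
#' @param n number of turbines (>= 0).
#' @param wind_power_class ordinal [raster_layer()] of wind power classes.
#' @param bias selection strength on the class (per class unit, >= 0 typical).
#' @param seed integer seed.
#' @param capacity_range_kw,rotor_range_m uniform attribute ranges.
#' @return data.frame: `id`, `x`, `y`, `capacity_kw`, `rotor_m`.
#' @export
generate_turbines <- function(n, wind_power_class, bias = 1, seed = 1L,
                              capacity_range_kw = c(1000, 3500),
                              rotor_range_m = c(70, 130)) {
  stopifnot(n >= 0, inherits(wind_power_class, "raster_layer"))
  g <- wind_power_class$grid
  if (n == 0)
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      capacity_kw = numeric(0), rotor_m = numeric(0)))
  v <- as.vector(wind_power_class$values)
  ok <- which(!is.na(v))
  withr::with_seed(seed, {
    cells <- sample(ok, n, replace = TRUE, prob = exp(bias * v[ok]))
    row <- ((cells - 1L) %% g$n_rows) + 1L
    col <- ((cells - 1L) %/% g$n_rows) + 1L
    ctr <- cell_centers(g, row, col)
    data.frame(id = seq_len(n), x = ctr$x, y = ctr$y,
               capacity_kw = stats::runif(n, capacity_range_kw[1], capacity_range_kw[2]),
               rotor_m = stats::runif(n, rotor_range_m[1], rotor_range_m[2]))
  })
}

#' @rdname generate_turbines
#' @param k number of roosts.
#' @param grid [grid_spec()] whose extent roosts are scattered over.
#' @export
generate_roosts <- function(k, grid, seed = 1L) {
  stopifnot(k >= 0, inherits(grid, "grid_spec"))
  if (k == 0) return(data.frame(id = integer(0), x = numeric(0), y = numeric(0)))
  withr::with_seed(seed, {
    data.frame(id = seq_len(k),
               x = grid$x_min + stats::runif(k) * grid$n_cols * grid$cell_size,
               y = grid$y_max - stats::runif(k) * grid$n_rows * grid$cell_size)
  })
}

#' Wrap sampled presences as raw occurrence records
#'
#' Emulates a museum-specimen download: each presence point becomes a record
#' with a year in `year_range`, a month drawn from its season's months, and a
#' basis-of-record that is `"PreservedSpecimen"` except for a `contamination`
#' fraction of `"HumanObservation"` records; a `missing_month` fraction lose
#' their month. Downstream cleaning is expected to remove the contaminants.
#'
#' @param season_points named list (season -> point table from
#'   [sample_presences()]).
#' @param seed integer seed.
#' @param year_range inclusive year bounds.
#' @param contamination fraction of non-specimen records.
#' @param missing_month fraction of records with month set to `NA`.
#' @return data.frame: `id`, `x`, `y`, `year`, `month`, `basis_of_record`.
#' @export
generate_occurrence_records <- function(season_points, seed = 1L,
                                        year_range = c(1970, 2020),
                                        contamination = 0.05,
                                        missing_month = 0.02) {
  months_of <- list(spring = 3:5, summer = 6:8, fall = 9:11, winter = c(12, 1, 2))
  withr::with_seed(seed, {
    recs <- lapply(names(season_points), function(season) {
      p <- season_points[[season]]
      if (!nrow(p)) return(NULL)
      data.frame(x = p$x, y = p$y,
                 year = sample(year_range[1]:year_range[2], nrow(p), replace = TRUE),
                 month = sample(months_of[[season]], nrow(p), replace = TRUE),
                 basis_of_record = ifelse(stats::runif(nrow(p)) < contamination,
                                          "HumanObservation", "PreservedSpecimen"))
    })
    df <- do.call(rbind, recs)
    df$month[stats::runif(nrow(df)) < missing_month] <- NA_integer_
    df <- df[sample(nrow(df)), ]  # shuffle so season blocks are not contiguous
    df$id <- seq_len(nrow(df))
    rownames(df) <- NULL
    df[, c("id", "x", "y", "year", "month", "basis_of_record")]
  })
}
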