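#' Training-omission suitability threshold
#'
#' The threshold at omission rate r is the `(floor(r m) + 1)`-th smallest of
#' the m training suitability values, so at most `floor(r m)` training
#' presences fall strictly below it. Deterministic under ties: with all
#' values equal the threshold is that value for any rate.
#'
#' @param train_suit numeric vector of suitability values at the (thinned)
#'   training presences.
#' @param rate omission rate in [0, 1).
#' @return Threshold value.
#' @export
omission_threshold <- function(train_suit, rate) {
  if (!length(train_suit)) stop("no training suitability values")
  stopifnot(rate >= 0, rate < 1)
  sort(train_suit)[floor(rate * length(train_suit)) + 1]
}

#' Seasonal omission thresholds
#'
#' @param train_suit training suitability values.
#' @param rates the two omission rates (lower, upper); defaults 10% and 50%.
#' @return list `t_low`, `t_high`, `m`, `rates`; `t_low <= t_high`.
#' @export
omission_thresholds <- function(train_suit, rates = c(0.10, 0.50)) {
  stopifnot(length(rates) == 2, rates[1] <= rates[2])
  list(t_low = omission_threshold(train_suit, rates[1]),
       t_high = omission_threshold(train_suit, rates[2]),
       m = length(train_suit), rates = rates)
}

#' Classify a suitability raster into three habitat classes
#'
#' Cells below the lower omission threshold are unsuitable (0), cells from
#' the lower threshold up to (excluding) the upper threshold are
#' low-to-moderate (1), and cells at or above the upper threshold are
#' high-suitability (2). Boundaries are half-open (`< t_low`, `>= t_high`) so
#' the classes are exhaustive and class is non-decreasing in suitability.
#' NoData propagates.
#'
#' @param suitability continuous [raster_layer()] in [0, 1].
#' @param thresholds list with `t_low`, `t_high` (see [omission_thresholds()]).
#' @param season optional season label carried in the result.
#' @return An object of class `habitat_class_map`: `raster` (ordinal layer
#'   with classes 0/1/2), `t_low`, `t_high`, `season`.
#' @export
classify_habitat <- function(suitability, thresholds, season = NA_character_) {
  stopifnot(inherits(suitability, "raster_layer"))
  t_low <- thresholds$t_low; t_high <- thresholds$t_high
  if (t_low > t_high) stop("t_low exceeds t_high")
  v <- suitability$values
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("suitability must lie in [0, 1]")
  cls <- ifelse(v < t_low, 0, ifelse(v < t_high, 1, 2))
  structure(list(raster = raster_layer(suitability$grid, cls, kind = "ordinal"),
                 t_low = t_low, t_high = t_high, season = season),
            class = "habitat_class_map")
}

#' @export
print.habitat_class_map <- function(x, ...) {
  tab <- table(factor(x$raster$values, levels = 0:2,
                      labels = c("unsuitable", "low-moderate", "high")))
  cat(sprintf("habitat_class_map (%s): thresholds %.4f / %.4f\n",
              x$season, x$t_low, x$t_high))
  print(tab)
  invisible(x)
}

habitat_class_labels <- c(`0` = "unsuitable", `1` = "low-moderate", `2` = "high")
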