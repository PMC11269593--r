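#' Filter raw occurrence records
#'
#' Keeps records whose year lies in `[year_min, year_max]` (inclusive) and
#' whose basis-of-record matches `basis` after normalization (case-insensitive,
#' ignoring separators, so `"PRESERVED_SPECIMEN"` matches
#' `"PreservedSpecimen"`). Records missing year or month are dropped; the
#' counts removed by each rule are attached as the `"filter_log"` attribute
#' and reported via `message()`, mirroring a record-funnel log.
#'
#' @param records data.frame with `year`, `month`, `basis_of_record` columns
#'   (plus coordinates and anything else, passed through).
#' @param year_min,year_max inclusive year bounds.
#' @param basis basis-of-record to retain.
#' @return Filtered data.frame with attribute `filter_log`.
#' @export
filter_occurrences <- function(records, year_min = 1970, year_max = 2020,
                               basis = "PreservedSpecimen") {
  norm <- function(s) gsub("[^a-z0-9]", "", tolower(as.character(s)))
  n0 <- nrow(records)
  miss <- is.na(records$year) | is.na(records$month)
  records <- records[!miss, , drop = FALSE]
  bad_year <- records$year < year_min | records$year > year_max
  records <- records[!bad_year, , drop = FALSE]
  bad_basis <- norm(records$basis_of_record) != norm(basis)
  records <- records[!bad_basis, , drop = FALSE]
  log <- list(input = n0, dropped_missing = sum(miss),
              dropped_year = sum(bad_year), dropped_basis = sum(bad_basis),
              kept = nrow(records))
  message(sprintf("occurrence filter: %d in, %d missing year/month, %d outside years, %d wrong basis, %d kept",
                  log$input, log$dropped_missing, log$dropped_year, log$dropped_basis, log$kept))
  attr(records, "filter_log") <- log
  records
}

#' Assign months to seasons
#'
#' Meteorological seasons: Mar-May spring, Jun-Aug summer, Sep-Nov fall,
#' Dec-Feb winter.
#'
#' @param month integer vector in 1..12.
#' @return Character vector of season names.
#' @export
assign_season <- function(month) {
  if (any(is.na(month)) || any(month < 1 | month > 12 | month != round(month)))
    stop("month must be an integer in 1..12")
  c("winter", "winter", "spring", "spring", "spring",
    "summer", "summer", "summer", "fall", "fall", "fall", "winter")[month]
}

#' Split records into seasonal sets
#'
#' @param records data.frame with a valid `month` column.
#' @return Named list of data.frames, one per season (possibly empty); every
#'   record lands in exactly one season.
#' @export
split_seasons <- function(records) {
  s <- assign_season(records$month)
  out <- lapply(c("spring", "summer", "fall", "winter"),
                function(k) records[s == k, , drop = FALSE])
  names(out) <- c("spring", "summer", "fall", "winter")
  out
}

#' Remove exact coordinate duplicates
#'
#' One record per exact coordinate pair, first by stable input order.
#'
#' @param records data.frame with `x`, `y`.
#' @return Deduplicated data.frame.
#' @export
dedupe_exact <- function(records) {
  records[!duplicated(records[, c("x", "y")]), , drop = FALSE]
}

#' Spatially rarefy records to a minimum-distance window
#'
#' Greedy thinning: repeatedly remove the record with the most neighbours
#' within `window_km`, ties broken by a seeded uniform draw, until no two
#' retained records lie within the window. The contract is the postcondition
#' (all pairwise distances >= `window_km`), not the heuristic; the procedure
#' is idempotent on its own output for a fixed seed.
#'
#' Distances: haversine (via geosphere) when `geographic = TRUE` and
#' coordinates are lon/lat degrees; Euclidean otherwise, with projected
#' map units assumed to be metres.
#'
#' @param records data.frame with `x`, `y`.
#' @param window_km minimum allowed pairwise distance, km.
#' @param seed integer seed for tie-breaking.
#' @param geographic logical; TRUE for lon/lat degree coordinates.
#' @return The retained subset, original order preserved.
#' @export
thin_spatial <- function(records, window_km = 10, seed = 1L, geographic = FALSE) {
  n <- nrow(records)
  if (n <= 1) return(records)
  d_km <- if (geographic) {
    geosphere::distm(as.matrix(records[, c("x", "y")])) / 1000
  } else {
    as.matrix(stats::dist(records[, c("x", "y")])) / 1000
  }
  close <- d_km < window_km
  diag(close) <- FALSE
  keep <- rep(TRUE, n)
  withr::with_seed(seed, {
    repeat {
      counts <- rowSums(close[, keep, drop = FALSE]) * keep
      if (!any(counts > 0)) break
      worst <- which(counts == max(counts))
      drop <- if (length(worst) > 1) sample(worst, 1) else worst
      keep[drop] <- FALSE
    }
  })
  records[keep, , drop = FALSE]
}

#' Prepare seasonal occurrence sets
#'
#' Full cleaning funnel: filter by year/basis/completeness, split into
#' seasons, and within each season drop exact coordinate duplicates and thin
#' to the distance window. Per-stage record counts are attached as the
#' `"funnel"` attribute.
#'
#' @inheritParams filter_occurrences
#' @inheritParams thin_spatial
#' @return Named list of cleaned seasonal data.frames with attribute `funnel`
#'   (data.frame of per-season counts at each stage).
#' @export
prep_occurrences <- function(records, year_min = 1970, year_max = 2020,
                             basis = "PreservedSpecimen", window_km = 10,
                             seed = 1L, geographic = FALSE) {
  filtered <- filter_occurrences(records, year_min, year_max, basis)
  seasons <- split_seasons(filtered)
  funnel <- data.frame(season = names(seasons),
                       filtered = vapply(seasons, nrow, integer(1)))
  seasons <- lapply(seasons, dedupe_exact)
  funnel$deduped <- vapply(seasons, nrow, integer(1))
  seasons <- lapply(seq_along(seasons), function(i)
    thin_spatial(seasons[[i]], window_km, seed + i, geographic))
  names(seasons) <- funnel$season
  funnel$thinned <- vapply(seasons, nrow, integer(1))
  attr(seasons, "funnel") <- funnel
  attr(seasons, "filter_log") <- attr(filtered, "filter_log")
  seasons
}
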