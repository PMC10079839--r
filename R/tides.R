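#' Water-level time series
#'
#' A tidy container for a tide-gauge record: a tibble with columns `time_h`
#' (hours since the record start, strictly increasing) and `level_cm` (water
#' level on a common vertical datum), carrying the station id and its
#' along-estuary axis position as attributes.
#'
#' @param time_h Numeric vector of times in hours, strictly increasing.
#' @param level_cm Water levels (cm).
#' @param station Station identifier.
#' @param position_m Along-estuary axis coordinate of the station (m).
#' @return A `water_level_series` tibble.
#' @export
water_level_series <- function(time_h, level_cm, station = "station",
                               position_m = 0) {
  if (length(time_h) != length(level_cm)) {
    abort_tm("`time_h` and `level_cm` must have equal length.",
             "invalid_argument")
  }
  if (length(time_h) > 1L && any(diff(time_h) <= 0)) {
    abort_tm("Timestamps must be strictly increasing.", "invalid_argument")
  }
  out <- tibble::tibble(time_h = as.numeric(time_h),
                        level_cm = as.numeric(level_cm))
  attr(out, "station") <- as.character(station)
  attr(out, "position_m") <- as.numeric(position_m)
  class(out) <- c("water_level_series", class(out))
  out
}

#' Extract high tides from a water-level series
#'
#' Local maxima of the level series (samples strictly greater than both
#' neighbours), thinned so that retained peaks are at least `min_separation`
#' hours apart; when two candidates fall inside one separation window the
#' higher one wins. The number of retained peaks is the total number of
#' tidal cycles in the record.
#'
#' @param series A [water_level_series()].
#' @param min_separation Minimum time between peaks (hours); the default of
#'   10 h suits a semidiurnal regime.
#' @return A tibble with columns `time_h` and `level_cm`, one row per high
#'   tide, ordered by time. Warns (and returns zero rows) when the series is
#'   monotone and has no interior maximum.
#' @examples
#' t <- seq(0, 124.2, by = 1 / 6)
#' s <- water_level_series(t, 200 * sin(2 * pi * t / 12.42))
#' nrow(extract_high_tides(s)) # 10 peaks in 10 M2 periods
#' @export
extract_high_tides <- function(series, min_separation = 10) {
  if (!is.numeric(min_separation) || min_separation <= 0) {
    abort_tm("`min_separation` must be positive.", "invalid_argument")
  }
  x <- series$level_cm
  t <- series$time_h
  n <- length(x)
  if (n < 3L) {
    warning("Series too short for peak detection; no high tides found.")
    return(tibble::tibble(time_h = numeric(), level_cm = numeric()))
  }
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  if (length(cand) == 0L) {
    warning("No local maxima found (monotone series?).")
    return(tibble::tibble(time_h = numeric(), level_cm = numeric()))
  }
  # keep the highest peaks first, drop any candidate within min_separation
  ord <- cand[order(-x[cand], t[cand])]
  kept_t <- numeric(0)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(t[i] - kept_t) >= min_separation)) {
      kept <- c(kept, i)
      kept_t <- c(kept_t, t[i])
    }
  }
  kept <- sort(kept)
  tibble::tibble(time_h = t[kept], level_cm = x[kept])
}

#' Percent of skipped tidal inundations at an elevation
#'
#' The fraction of high tides whose peak level does not reach above a given
#' elevation: `(1 - cycles_inundated / cycles_total) * 100`. A tide
#' inundates an elevation only when its peak is strictly greater than the
#' elevation, so a peak exactly at the elevation counts as skipped.
#'
#' @param high_tide_levels Numeric vector of high-tide peak levels (cm).
#' @param elevation Elevation(s) (cm, same datum); vectorised.
#' @return Percent skipped in `[0, 100]`, one value per elevation.
#' @examples
#' skipped_fraction(c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100), 60)
#' @export
skipped_fraction <- function(high_tide_levels, elevation) {
  if (length(high_tide_levels) == 0L) {
    abort_tm("No high tides: the skipped-inundation metric is undefined.",
             "undefined_metric")
  }
  srt <- sort(high_tide_levels)
  total <- length(srt)
  inundated <- total - findInterval(elevation, srt)
  (1 - inundated / total) * 100
}

#' Exposure curve: skipped inundations as a function of elevation
#'
#' Builds the monotone map from elevation to the percent of skipped tidal
#' inundations for one station. The curve is a right-continuous step
#' function with steps exactly at the high-tide peak levels; it is evaluated
#' exactly from the retained peaks, not from the tabulated grid.
#'
#' @param series A [water_level_series()].
#' @param elevation_grid Elevations (cm) at which to tabulate the curve;
#'   defaults to the sorted unique peak levels.
#' @param min_separation Passed to [extract_high_tides()].
#' @return An `exposure_curve`: a tibble with columns `elevation_cm` and
#'   `skipped_pct`, with the peak levels, cycle count, station and position
#'   as attributes.
#' @export
exposure_curve <- function(series, elevation_grid = NULL,
                           min_separation = 10) {
  peaks <- extract_high_tides(series, min_separation)
  if (nrow(peaks) == 0L) {
    abort_tm("No high tides: cannot build an exposure curve.",
             "undefined_metric")
  }
  if (is.null(elevation_grid)) {
    elevation_grid <- sort(unique(peaks$level_cm))
  }
  elevation_grid <- sort(elevation_grid)
  out <- tibble::tibble(
    elevation_cm = elevation_grid,
    skipped_pct = skipped_fraction(peaks$level_cm, elevation_grid)
  )
  attr(out, "peak_levels") <- sort(peaks$level_cm)
  attr(out, "n_cycles_total") <- nrow(peaks)
  attr(out, "station") <- attr(series, "station")
  attr(out, "position_m") <- attr(series, "position_m")
  class(out) <- c("exposure_curve", class(out))
  out
}

#' Evaluate an exposure curve at arbitrary elevations
#'
#' Station curves are evaluated exactly from their retained peak levels;
#' interpolated curves as the position-weighted mix of their two parent
#' station curves.
#'
#' @param curve An `exposure_curve`.
#' @param elevation Elevations (cm); vectorised.
#' @return Percent skipped at each elevation.
#' @export
eval_exposure <- function(curve, elevation) {
  peaks <- attr(curve, "peak_levels")
  if (!is.null(peaks)) {
    return(skipped_fraction(peaks, elevation))
  }
  parents <- attr(curve, "parents")
  if (!is.null(parents)) {
    w <- attr(curve, "weight")
    return((1 - w) * eval_exposure(parents[[1]], elevation) +
             w * eval_exposure(parents[[2]], elevation))
  }
  # tabulated curve only: right-continuous step interpolation
  approx(curve$elevation_cm, curve$skipped_pct, xout = elevation,
         method = "constant", f = 0, rule = 2,
         yleft = 0)$y
}

#' Interpolate exposure curves along the estuary axis
#'
#' Per-elevation linear interpolation of percent skipped between the two
#' stations bracketing `query_position`; outside the covered range the
#' nearest station's curve is used unchanged.
#'
#' @param curves List of `exposure_curve`s with distinct axis positions.
#' @param query_position Axis coordinate (m) of the query.
#' @return An `exposure_curve` at the query position.
#' @export
interpolate_exposure <- function(curves, query_position) {
  if (length(curves) == 0L) {
    abort_tm("Need at least one exposure curve.", "invalid_argument")
  }
  pos <- vapply(curves, function(cv) attr(cv, "position_m"), numeric(1))
  ord <- order(pos)
  curves <- curves[ord]
  pos <- pos[ord]
  if (query_position <= pos[1]) return(curves[[1]])
  if (query_position >= pos[length(pos)]) return(curves[[length(curves)]])
  j <- findInterval(query_position, pos)
  if (pos[j] == query_position) return(curves[[j]])
  a <- curves[[j]]; b <- curves[[j + 1L]]
  w <- (query_position - pos[j]) / (pos[j + 1L] - pos[j])
  grid <- sort(unique(c(a$elevation_cm, b$elevation_cm)))
  out <- tibble::tibble(
    elevation_cm = grid,
    skipped_pct = (1 - w) * eval_exposure(a, grid) + w * eval_exposure(b, grid)
  )
  attr(out, "parents") <- list(a, b)
  attr(out, "weight") <- w
  attr(out, "position_m") <- query_position
  attr(out, "station") <- paste0(attr(a, "station"), "|", attr(b, "station"))
  class(out) <- c("exposure_curve", class(out))
  out
}

#' Per-cell percent of skipped tidal inundations
#'
#' Converts an elevation raster into the skipped-inundation raster using one
#' or more station exposure curves, interpolated along the estuary axis
#' (each cell's map x coordinate by default). Nodata propagates.
#'
#' @param dem Elevation `grid_raster` (cm, same datum as the water levels).
#' @param curves List of `exposure_curve`s (or a single curve).
#' @param axis_coordinates Optional per-column axis coordinates; defaults to
#'   the cells' map x coordinates.
#' @return A `grid_raster` of kind `"skipped"`.
#' @export
exposure_raster <- function(dem, curves, axis_coordinates = NULL) {
  if (grid_kind(dem) != "elevation") {
    abort_tm(paste("exposure_raster() needs a grid_raster of kind",
                   "\"elevation\" on the water-level datum."),
             "semantic_type")
  }
  if (inherits(curves, "exposure_curve")) curves <- list(curves)
  if (length(curves) == 0L) {
    abort_tm("Need at least one exposure curve.", "invalid_argument")
  }
  if (is.null(axis_coordinates)) axis_coordinates <- axis_coords(dem)
  z <- as_plain_matrix(dem)
  out <- matrix(NA_real_, nrow(z), ncol(z))
  # cells in one column share an axis coordinate, hence a curve
  for (ux in unique(axis_coordinates)) {
    cols <- which(axis_coordinates == ux)
    cv <- if (length(curves) == 1L) curves[[1]] else {
      interpolate_exposure(curves, ux)
    }
    vals <- z[, cols, drop = FALSE]
    ok <- !is.na(vals)
    res <- vals
    res[ok] <- eval_exposure(cv, vals[ok])
    out[, cols] <- res
  }
  grid_like(dem, out, kind = "skipped")
}

#' Read and write water-level tables
#'
#' CSV schema: `station, position_m, timestamp_iso8601, level_cm`.
#' Timestamps are converted to hours since the earliest timestamp in the
#' file.
#'
#' @param series_list List of [water_level_series()].
#' @param path CSV path.
#' @param epoch POSIXct origin used to render `time_h` as timestamps.
#' @return `write_water_levels()` returns `path` invisibly;
#'   `read_water_levels()` returns a list of `water_level_series`.
#' @export
write_water_levels <- function(series_list, path,
                               epoch = as.POSIXct("2020-01-01 00:00:00",
                                                  tz = "UTC")) {
  if (inherits(series_list, "water_level_series")) {
    series_list <- list(series_list)
  }
  rows <- purrr::map_dfr(series_list, function(s) {
    tibble::tibble(
      station = attr(s, "station"),
      position_m = attr(s, "position_m"),
      timestamp_iso8601 = format(epoch + s$time_h * 3600,
                                 "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      level_cm = s$level_cm
    )
  })
  readr::write_csv(rows, path)
  invisible(path)
}

#' @rdname write_water_levels
#' @export
read_water_levels <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  t0 <- min(as.POSIXct(df$timestamp_iso8601, tz = "UTC",
                       format = "%Y-%m-%dT%H:%M:%SZ"))
  df$time_h <- as.numeric(difftime(
    as.POSIXct(df$timestamp_iso8601, tz = "UTC",
               format = "%Y-%m-%dT%H:%M:%SZ"), t0, units = "hours"))
  split(df, df$station) |>
    lapply(function(d) {
      water_level_series(d$time_h, d$level_cm, station = d$station[1],
                         position_m = d$position_m[1])
    }) |>
    unname()
}
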