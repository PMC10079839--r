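#' Micro-topographic pattern intensity from NIR imagery
#'
#' The intensity of micro-topography is the sample standard deviation of
#' the near-infrared band inside 10 x 10 m frames. Fine ridge-runnel relief
#' modulates surface wetness and hence NIR reflectance, so windowed NIR
#' variability is a proxy for metre-scale bed relief even when the relief
#' is below the vertical resolution of the available elevation data. If the
#' NIR band is missing, a declared alternate band may be used with a
#' provenance warning (other bands and greyscale give similar results).
#'
#' @param img An [ortho_image()], or a `grid_raster` of a single band.
#' @param window Frame edge length (m), default 10.
#' @param band Band to use when `img` lacks NIR: `"red"` or `"green"`.
#' @return An intensity `grid_raster` at `window` resolution (values >= 0),
#'   with the source band and year recorded as attributes.
#' @export
intensity <- function(img, window = 10, band = "nir") {
  if (inherits(img, "ortho_image")) {
    src <- img[[band]]
    if (is.null(src)) abort_tm("Requested band is missing.", "invalid_input")
    if (band != "nir") {
      warning("NIR band not used; intensity computed on the ", band,
              " band (similar, but flagged for provenance).")
    }
    year <- img$year
  } else {
    src <- img
    year <- NA_integer_
  }
  out <- focal_sd(src, window)
  attr(out, "band") <- band
  attr(out, "year") <- year
  out
}

#' Exclusion mask for the micro-topography analysis
#'
#' Builds the union of the three exclusions applied before any
#' micro-topography statistic: (1) vegetated cells, (2) cells at or below
#' neap high water level (percent skipped inundations equal to zero),
#' where mega-ripples would contaminate the signal, and (3) tidal creeks,
#' detected as slope > 3 degrees at 2 m resolution and block-max resampled
#' to 10 m so that creek-adjacent cells are excluded as well.
#'
#' @param veg Logical vegetation `grid_raster` at 10 m (or finer; it is
#'   max-resampled to 10 m).
#' @param exposure Percent-skipped `grid_raster` at 10 m (or finer;
#'   mean-resampled).
#' @param slope_fine Slope `grid_raster` (degrees) at a resolution finer
#'   than 10 m (2 m in the reference procedure).
#' @param creek_cutoff_deg Creek slope cutoff (degrees), default 3.
#' @param target_cell Output resolution (m), default 10.
#' @return A logical exclusion `grid_raster` at `target_cell` resolution
#'   (`TRUE` = excluded).
#' @export
analysis_mask <- function(veg, exposure, slope_fine, creek_cutoff_deg = 3,
                          target_cell = 10) {
  if (cell_size(slope_fine) >= target_cell) {
    abort_tm("Creek slope must be supplied at finer than output resolution.",
             "invalid_argument")
  }
  veg10 <- if (cell_size(veg) < target_cell) {
    block_resample(veg, target_cell, "max")
  } else veg
  exp10 <- if (cell_size(exposure) < target_cell) {
    block_resample(exposure, target_cell, "mean")
  } else exposure
  creek_fine <- grid_like(slope_fine,
                          as_plain_matrix(slope_fine) > creek_cutoff_deg,
                          kind = "mask")
  creek10 <- block_resample(creek_fine, target_cell, "max")
  v <- as_plain_matrix(veg10); v[is.na(v)] <- FALSE
  e <- as_plain_matrix(exp10)
  c10 <- as_plain_matrix(creek10); c10[is.na(c10)] <- FALSE
  excl <- (v > 0) | (is.na(e) | e == 0) | (c10 > 0)
  grid_raster(excl, cell_size = target_cell, origin = grid_origin(veg10),
              kind = "mask")
}

#' Calibrate image-based intensity against slope variability
#'
#' Validates the NIR-variability proxy against elevation data: the SD of
#' NIR (the intensity) is regressed on the SD of local slope (from a
#' high-resolution DEM, aggregated to 10 m tiles), as ordinary least squares after
#' log-transforming both variables. Non-positive values (which have no
#' logarithm) are dropped and counted.
#'
#' @param sd_slope_10m `grid_raster`: per-10 m-tile SD of local slope.
#' @param intensity_10m `grid_raster`: per-10 m-tile SD of NIR
#'   ([intensity()] output).
#' @return A `calibration_fit` with the log-log slope and intercept, R^2,
#'   F statistic and n; `tidy()` and `glance()` methods apply.
#' @export
calibrate_intensity <- function(sd_slope_10m, intensity_10m) {
  check_coregistered(sd_slope_10m, intensity_10m,
                     "slope-SD and intensity rasters")
  x <- as.vector(as_plain_matrix(sd_slope_10m))
  y <- as.vector(as_plain_matrix(intensity_10m))
  ok <- !is.na(x) & !is.na(y)
  pos <- ok & x > 0 & y > 0
  n_dropped <- sum(ok) - sum(pos)
  if (sum(pos) < 3L) {
    abort_tm("Fewer than 3 positive paired cells; cannot calibrate.",
             "insufficient_data")
  }
  fit <- lm(log(y[pos]) ~ log(x[pos]))
  sm <- suppressWarnings(summary(fit))
  structure(list(
    fit = fit,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    f_statistic = unname(sm$fstatistic[1]),
    df = unname(sm$fstatistic[2:3]),
    n = sum(pos),
    n_dropped_nonpositive = n_dropped
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(paste0("<calibration_fit> log-log slope: %.3f, R^2: %.3f,",
                     " F(%d,%d) = %.1f, n = %d\n"),
              x$slope, x$r_squared, x$df[1], x$df[2], x$f_statistic, x$n))
  invisible(x)
}

#' @export
tidy.calibration_fit <- function(x, ...) broom::tidy(x$fit, ...)

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r.squared = x$r_squared,
    f.statistic = x$f_statistic, df = x$df[1], df.residual = x$df[2],
    n = x$n, n_dropped_nonpositive = x$n_dropped_nonpositive
  )
}

#' Export a calibration fit as a JSON report
#'
#' @param x A `calibration_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(x, path) {
  jsonlite::write_json(
    list(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, f_statistic = x$f_statistic,
         df = x$df, n = x$n,
         n_dropped_nonpositive = x$n_dropped_nonpositive),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
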