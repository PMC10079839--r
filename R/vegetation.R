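#' False-colour orthophoto
#'
#' Bundles the co-registered NIR and Red (and optionally Green) reflectance
#' bands of one aerial campaign.
#'
#' @param nir,red,green `grid_raster`s of kind `"reflectance"`; `green` may
#'   be `NULL`.
#' @param year Campaign year (integer).
#' @return An `ortho_image`.
#' @export
ortho_image <- function(nir, red, green = NULL, year = NA_integer_) {
  if (is.null(nir) || is.null(red)) {
    abort_tm("Both NIR and Red bands are required.", "invalid_input")
  }
  check_coregistered(nir, red, "NIR and Red bands")
  if (!is.null(green)) check_coregistered(nir, green, "NIR and Green bands")
  structure(list(nir = nir, red = red, green = green,
                 year = as.integer(year), resolution = cell_size(nir)),
            class = "ortho_image")
}

#' @export
print.ortho_image <- function(x, ...) {
  cat(sprintf("<ortho_image %d x %d> year: %s, resolution: %g m, bands: %s\n",
              nrow(x$nir), ncol(x$nir),
              ifelse(is.na(x$year), "?", x$year), x$resolution,
              paste(c("NIR", "Red", if (!is.null(x$green)) "Green"),
                    collapse = ", ")))
  invisible(x)
}

#' Normalized difference vegetation index
#'
#' `(NIR - Red) / (NIR + Red)` per cell. Cells where both bands sum to zero
#' are nodata; nodata in either band propagates.
#'
#' @param img An [ortho_image()].
#' @return A `grid_raster` with values in `[-1, 1]`.
#' @export
ndvi <- function(img) {
  if (!inherits(img, "ortho_image")) {
    abort_tm("`img` must be an ortho_image with NIR and Red bands.",
             "invalid_input")
  }
  nir <- as_plain_matrix(img$nir)
  red <- as_plain_matrix(img$red)
  denom <- nir + red
  out <- (nir - red) / denom
  out[!is.na(denom) & denom == 0] <- NA
  grid_like(img$nir, out, kind = "other")
}

#' Per-scene NDVI classification threshold from bimodal peak analysis
#'
#' Fits a Gaussian kernel density (Silverman's bandwidth) to the NDVI
#' sample of one scene, finds its modes, keeps those whose prominence is at
#' least `prominence_floor` of the density maximum, and places the
#' classification threshold half-way between the two most prominent modes:
#' the lower is the sediment peak, the upper the vegetation peak. Because
#' atmospheric state and season shift NDVI between campaigns, a threshold
#' is fitted per scene and never pooled across years.
#'
#' @param ndvi_values Numeric vector of valid NDVI cell values (at least
#'   1e4 recommended).
#' @param prominence_floor Minimum mode prominence as a fraction of the
#'   maximum density (default 0.05).
#' @param bw Kernel bandwidth; default Silverman's rule (`"nrd0"`).
#' @return An `ndvi_threshold` with fields `sediment_peak`,
#'   `vegetation_peak`, `threshold` and `diagnostics`. Signals a
#'   `tidalmarsh_unimodal` error when fewer than two prominent modes exist;
#'   callers may then supply a manual threshold.
#' @export
fit_ndvi_threshold <- function(ndvi_values, prominence_floor = 0.05,
                               bw = "nrd0") {
  v <- ndvi_values[is.finite(ndvi_values)]
  if (length(v) < 10L) {
    abort_tm("Too few NDVI values for peak analysis.", "insufficient_data")
  }
  d <- density(v, bw = bw, n = 1024)
  y <- d$y
  n <- length(y)
  peaks <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(peaks) == 0L) peaks <- which.max(y)
  prom <- vapply(peaks, function(p) {
    higher <- peaks[y[peaks] > y[p]]
    left <- higher[higher < p]
    right <- higher[higher > p]
    saddle_l <- if (length(left)) min(y[max(left):p]) else min(y[1:p])
    saddle_r <- if (length(right)) min(y[p:min(right)]) else min(y[p:n])
    # prominence: drop to the higher of the two key saddles; the global
    # mode keys off the density floor on either side
    if (length(left) == 0L && length(right) == 0L) {
      y[p] - min(saddle_l, saddle_r)
    } else if (length(left) == 0L) {
      y[p] - saddle_r
    } else if (length(right) == 0L) {
      y[p] - saddle_l
    } else {
      y[p] - max(saddle_l, saddle_r)
    }
  }, numeric(1))
  keep <- peaks[prom >= prominence_floor * max(y)]
  if (length(keep) < 2L) {
    abort_tm(paste("NDVI distribution has fewer than two prominent modes;",
                   "supply a manual threshold."), "unimodal")
  }
  top2 <- keep[order(-prom[match(keep, peaks)])][1:2]
  sed <- d$x[min(top2)]
  veg <- d$x[max(top2)]
  structure(list(
    sediment_peak = sed,
    vegetation_peak = veg,
    threshold = (sed + veg) / 2,
    diagnostics = list(bandwidth = d$bw, n = length(v),
                       n_modes = length(keep),
                       prominences = prom[match(top2, peaks)],
                       prominence_floor = prominence_floor)
  ), class = "ndvi_threshold")
}

#' @export
print.ndvi_threshold <- function(x, ...) {
  cat(sprintf(paste0("<ndvi_threshold> sediment peak: %.3f, vegetation",
                     " peak: %.3f, threshold: %.3f\n"),
              x$sediment_peak, x$vegetation_peak, x$threshold))
  invisible(x)
}

#' @export
tidy.ndvi_threshold <- function(x, ...) {
  tibble::tibble(
    sediment_peak = x$sediment_peak,
    vegetation_peak = x$vegetation_peak,
    threshold = x$threshold,
    bandwidth = x$diagnostics$bandwidth,
    n = x$diagnostics$n
  )
}

#' Classify vegetation presence from NDVI
#'
#' A cell is vegetated when its NDVI strictly exceeds the threshold; a cell
#' exactly at the threshold is sediment. Nodata propagates.
#'
#' @param ndvi_raster A `grid_raster` of NDVI values.
#' @param thr An [fit_ndvi_threshold()] object or a bare number in (-1, 1).
#' @return A logical `grid_raster` (kind `"mask"`).
#' @export
classify_vegetation <- function(ndvi_raster, thr) {
  th <- if (inherits(thr, "ndvi_threshold")) thr$threshold else thr
  if (!is.numeric(th) || th <= -1 || th >= 1) {
    abort_tm("Threshold must lie in (-1, 1).", "invalid_argument")
  }
  m <- as_plain_matrix(ndvi_raster)
  grid_like(ndvi_raster, m > th, kind = "mask")
}

#' Newly established vegetation between two campaigns
#'
#' Vegetation present in the later year but not in the earlier. Nodata in
#' either year is nodata in the result, mirroring the exclusion of cells
#' without complete coverage.
#'
#' @param mask_early,mask_late Logical `grid_raster`s, co-registered.
#' @param year_early,year_late Optional campaign years; must differ when
#'   both given.
#' @return A logical `grid_raster` of new establishment.
#' @export
new_establishment <- function(mask_early, mask_late,
                              year_early = NULL, year_late = NULL) {
  check_coregistered(mask_early, mask_late, "vegetation masks")
  if (!is.null(year_early) && !is.null(year_late)) {
    if (year_early >= year_late) {
      abort_tm("`year_early` must precede `year_late`.", "invalid_argument")
    }
  }
  e <- as_plain_matrix(mask_early)
  l <- as_plain_matrix(mask_late)
  out <- l & !e
  out[is.na(e) | is.na(l)] <- NA
  grid_like(mask_early, out, kind = "mask")
}
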