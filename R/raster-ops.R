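#' Terrain slope in degrees (Horn's method)
#'
#' Computes the local slope of an elevation grid with Horn's 3x3
#' finite-difference gradient, the default of the standard GIS `terrain`
#' routines. Elevations are in cm and cell size in m; both are converted to a
#' common unit before taking the arc-tangent, so a 1 % grade returns
#' `atan(0.01) * 180 / pi` = 0.5729 degrees. Border cells are nodata.
#'
#' @param dem A `grid_raster` of kind `"elevation"` (cm), at least 3 x 3.
#' @return A `grid_raster` of kind `"slope"` (degrees).
#' @examples
#' z <- outer(rep(0, 12), seq_len(12) - 1) # 1 cm rise per 1 m cell = 1 % grade
#' slope_deg(grid_raster(z, kind = "elevation"))
#' @export
slope_deg <- function(dem) {
  if (!is_grid_raster(dem) || grid_kind(dem) != "elevation") {
    abort_tm("slope_deg() needs a grid_raster of kind \"elevation\".",
             "semantic_type")
  }
  if (nrow(dem) < 3L || ncol(dem) < 3L) {
    abort_tm("slope_deg() needs at least a 3 x 3 grid.", "invalid_argument")
  }
  z <- as_plain_matrix(dem) / 100 # cm -> m
  nr <- nrow(z); nc <- ncol(z)
  cs <- cell_size(dem)
  # 3x3 neighbourhood shifts of the interior
  sh <- function(dr, dc) z[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
  # Horn weights: dz/dx from the east minus west columns, 1-2-1 weighted
  dzdx <- ((sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
             (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))) / (8 * cs)
  dzdy <- ((sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
             (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))) / (8 * cs)
  out <- matrix(NA_real_, nr, nc)
  out[2:(nr - 1), 2:(nc - 1)] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  grid_like(dem, out, kind = "slope")
}

block_stats <- function(m, f) {
  # pad to a multiple of f, reshape so each block is one column
  nr <- nrow(m); nc <- ncol(m)
  nr2 <- ceiling(nr / f); nc2 <- ceiling(nc / f)
  p <- matrix(NA_real_, nr2 * f, nc2 * f)
  p[seq_len(nr), seq_len(nc)] <- m
  a <- aperm(array(p, c(f, nr2, f, nc2)), c(1, 3, 2, 4))
  dim(a) <- c(f * f, nr2 * nc2)
  valid <- !is.na(a)
  n <- colSums(valid)
  s1 <- colSums(a, na.rm = TRUE)
  # two-pass (centred) sum of squares: exact zero on constant blocks
  mu <- ifelse(n > 0, s1 / n, 0)
  ss <- colSums(sweep(a, 2L, mu, `-`)^2, na.rm = TRUE)
  list(a = a, n = n, s1 = s1, ss = ss, nr2 = nr2, nc2 = nc2)
}

#' Aggregate a raster into coarser non-overlapping blocks
#'
#' @param r A `grid_raster`.
#' @param target_cell Target cell size (m); must be an integer multiple of
#'   the source cell size.
#' @param aggregator `"mean"`, `"max"` or `"sd"` (sample SD, n - 1). Mean
#'   uses whatever valid cells a block holds; max and sd return nodata for
#'   blocks with fewer than 2 valid cells.
#' @return A `grid_raster` at `target_cell` resolution.
#' @export
block_resample <- function(r, target_cell, aggregator = c("mean", "max", "sd")) {
  aggregator <- match.arg(aggregator)
  cs <- cell_size(r)
  f <- target_cell / cs
  if (abs(f - round(f)) > 1e-9 || f < 1) {
    abort_tm("`target_cell` must be an integer multiple of the cell size.",
             "invalid_argument")
  }
  f <- as.integer(round(f))
  m <- as_plain_matrix(r)
  logical_in <- is.logical(m)
  if (logical_in) m <- m * 1
  bs <- block_stats(m, f)
  out <- switch(
    aggregator,
    mean = ifelse(bs$n > 0, bs$s1 / bs$n, NA_real_),
    max = {
      mx <- suppressWarnings(apply(bs$a, 2L, max, na.rm = TRUE))
      ifelse(bs$n >= 2, mx, NA_real_)
    },
    sd = ifelse(bs$n >= 2, sqrt(bs$ss / (bs$n - 1)), NA_real_)
  )
  out <- matrix(out, bs$nr2, bs$nc2)
  kind <- grid_kind(r)
  if (logical_in && aggregator == "max") {
    out <- matrix(as.logical(out), nrow(out))
  } else if (kind == "mask") {
    kind <- "other"
  }
  grid_raster(out, cell_size = f * cs, origin = grid_origin(r), kind = kind)
}

#' Windowed standard deviation (focal SD)
#'
#' Sample standard deviation of the valid cells inside each non-overlapping
#' `window` x `window` metre tile; the output grid is at window resolution.
#' This is the micro-topographic intensity primitive: the SD of near-infrared
#' reflectance in 10 x 10 m frames. A moving-window variant (output at source
#' resolution, centred windows) is available with `tiles = FALSE`.
#'
#' @param r A `grid_raster`.
#' @param window Window edge length (m); integer multiple of the cell size.
#' @param tiles If `TRUE` (default), non-overlapping tiles; if `FALSE`, a
#'   centred moving window.
#' @return A `grid_raster`. Windows with fewer than 2 valid cells are nodata.
#' @export
focal_sd <- function(r, window, tiles = TRUE) {
  cs <- cell_size(r)
  if (window < cs) {
    abort_tm("`window` must be at least the cell size.", "invalid_argument")
  }
  if (tiles) {
    out <- block_resample(r, window, aggregator = "sd")
    attr(out, "kind") <- "other"
    return(out)
  }
  f <- as.integer(round(window / cs))
  if (abs(window / cs - f) > 1e-9) {
    abort_tm("`window` must be an integer multiple of the cell size.",
             "invalid_argument")
  }
  m <- as_plain_matrix(r)
  valid <- !is.na(m)
  mz <- ifelse(valid, m, 0)
  # integral-image running sums for moving-window n, sum and sum of squares
  half_lo <- (f - 1L) %/% 2L
  half_hi <- f - 1L - half_lo
  box <- function(x) {
    nr <- nrow(x); nc <- ncol(x)
    cum <- apply(apply(x, 2L, cumsum), 1L, cumsum) # t(cumsum both dims)
    cum <- t(cum)
    padded <- matrix(0, nr + 1L, nc + 1L)
    padded[-1L, -1L] <- cum
    r1 <- pmax(seq_len(nr) - half_lo, 1L); r2 <- pmin(seq_len(nr) + half_hi, nr)
    c1 <- pmax(seq_len(nc) - half_lo, 1L); c2 <- pmin(seq_len(nc) + half_hi, nc)
    padded[r2 + 1L, c2 + 1L, drop = FALSE] -
      padded[r1, c2 + 1L, drop = FALSE] -
      padded[r2 + 1L, c1, drop = FALSE] +
      padded[r1, c1, drop = FALSE]
  }
  n <- box(valid * 1)
  s1 <- box(mz)
  s2 <- box(mz^2)
  out <- ifelse(n >= 2, sqrt(pmax(s2 - s1^2 / n, 0) / (n - 1)), NA_real_)
  grid_like(r, out, kind = "other")
}

#' Exclude masked areas from a raster
#'
#' Cells flagged `TRUE` by any of the supplied masks become nodata. The
#' result is independent of mask order and applying the union of masks once
#' gives the same answer as applying them one by one.
#'
#' @param r A `grid_raster`.
#' @param masks A list of logical `grid_raster`s co-registered with `r`.
#' @return `r` with flagged cells set to nodata.
#' @export
apply_masks <- function(r, masks) {
  if (length(masks) == 0L) return(r)
  m <- as_plain_matrix(r)
  for (mk in masks) {
    check_coregistered(r, mk, "raster and mask")
    flag <- as_plain_matrix(mk)
    flag[is.na(flag)] <- FALSE
    m[flag > 0] <- NA
  }
  grid_like(r, m)
}
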