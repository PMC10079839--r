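hyps_values <- function(values) {
  v <- sort(values)
  n <- length(v)
  uv <- unique(v)
  # relative area >= each value; vectorised via the ECDF complement
  ge <- n - findInterval(uv, v, left.open = TRUE)
  tibble::tibble(value = uv, rel_area_pct = 100 * ge / n)
}

#' Hypsometric curve of skipped tidal inundations
#'
#' For the intertidal area above neap high water (cells with a positive
#' percent of skipped inundations), the relative area (% of those cells)
#' that equals or exceeds each observed value. The curve opens at 100 %
#' and is non-increasing.
#'
#' @param exposure Percent-skipped `grid_raster`.
#' @param year Optional year label attached to the curve.
#' @return A `hypsometric_curve` tibble with columns `skipped_pct` and
#'   `rel_area_pct`.
#' @export
hypsometric_curve <- function(exposure, year = NA) {
  v <- as.vector(as_plain_matrix(exposure))
  v <- v[!is.na(v) & v > 0]
  if (length(v) == 0L) {
    abort_tm("No valid cells above neap high water.", "insufficient_data")
  }
  out <- hyps_values(v)
  names(out) <- c("skipped_pct", "rel_area_pct")
  out$year <- year
  class(out) <- c("hypsometric_curve", class(out))
  out
}

#' @export
autoplot.hypsometric_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$skipped_pct,
                                       y = .data$rel_area_pct)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "skipped tidal inundations (%)",
                  y = "relative area (%)")
}

#' Slope hypsometry by tidal position
#'
#' Cells are grouped into bins of percent skipped inundations and a
#' hypsometric curve of the tidal-flat slope is built per bin, showing
#' whether flats lying higher in the tidal frame are flatter.
#'
#' @param slope Slope `grid_raster` (degrees), co-registered with
#'   `exposure`.
#' @param exposure Percent-skipped `grid_raster`.
#' @param position_bins Upper edges of the skipped-percent bins; together
#'   with 0 they must cover (0, 100].
#' @return A tibble with `bin_low`, `bin_high`, `slope_deg`,
#'   `rel_area_pct` and per-bin `n`. Empty bins yield no rows and are
#'   reported in a message.
#' @export
slope_hypsometry <- function(slope, exposure,
                             position_bins = c(0.01, 0.1, 1, 5, 10, 25, 50,
                                               100)) {
  check_coregistered(slope, exposure, "slope and exposure")
  edges <- unique(c(0, sort(position_bins)))
  s <- as.vector(as_plain_matrix(slope))
  e <- as.vector(as_plain_matrix(exposure))
  ok <- !is.na(s) & !is.na(e) & e > 0
  s <- s[ok]; e <- e[ok]
  bin <- findInterval(e, edges, left.open = TRUE, rightmost.closed = TRUE)
  out <- purrr::map_dfr(seq_len(length(edges) - 1L), function(b) {
    sel <- bin == b
    if (!any(sel)) return(tibble::tibble())
    h <- hyps_values(s[sel])
    tibble::tibble(bin_low = edges[b], bin_high = edges[b + 1L],
                   slope_deg = h$value, rel_area_pct = h$rel_area_pct,
                   n = sum(sel))
  })
  empty <- setdiff(seq_len(length(edges) - 1L), unique(bin))
  if (length(empty)) {
    message("Empty skipped-percent bins: ",
            paste(sprintf("(%g, %g]", edges[empty], edges[empty + 1L]),
                  collapse = ", "))
  }
  out
}

#' Linear trend of an annual series
#'
#' Ordinary least squares of a yearly mean value on year, as used for the
#' accretion rate (cm per year) and the rise in mean percent skipped
#' inundations of flats above neap high water.
#'
#' @param data A data frame with columns `year` and `value`, or a numeric
#'   vector of years.
#' @param value Values when `data` is a vector of years.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return A `trend_fit`; `tidy()` and `glance()` methods apply. The
#'   standard error and interval are reported only for 3 or more years.
#' @export
annual_trend <- function(data, value = NULL, conf_level = 0.95) {
  if (is.data.frame(data)) {
    years <- data$year
    values <- data$value
  } else {
    years <- data
    values <- value
  }
  ok <- !is.na(years) & !is.na(values)
  years <- years[ok]; values <- values[ok]
  if (length(unique(years)) < 2L) {
    abort_tm("Need at least 2 distinct years for a trend.",
             "invalid_argument")
  }
  fit <- lm(values ~ years)
  n <- length(years)
  slope <- unname(coef(fit)[2])
  if (n >= 3L) {
    se <- suppressWarnings(summary(fit)$coefficients[2, 2])
    ci <- suppressWarnings(confint(fit, "years", level = conf_level))
    # a perfect fit has zero residual variance; the interval collapses
    if (!is.finite(se)) se <- 0
    ci[!is.finite(ci)] <- slope
  } else {
    se <- NA_real_
    ci <- matrix(c(NA_real_, NA_real_), 1)
  }
  structure(list(fit = fit, slope = slope, se = se,
                 intercept = unname(coef(fit)[1]),
                 ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level, n = n),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> slope: %.4g per year (SE %.4g), n = %d years\n",
              x$slope, x$se, x$n))
  invisible(x)
}

#' @export
tidy.trend_fit <- function(x, ...) broom::tidy(x$fit, ...)

#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, se = x$se, intercept = x$intercept,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 conf_level = x$conf_level, n = x$n)
}

#' Mean micro-topography intensity in logarithmic slope bins
#'
#' Divides slope into `n_bins` logarithmically spaced bins (default 120
#' between 0.01 and 10 degrees) and reports the mean intensity, its
#' standard error and the cell count per bin. Inputs should already be
#' masked ([analysis_mask()]). Empty bins keep their row with missing
#' statistics rather than zeros.
#'
#' @param intensity_r Intensity `grid_raster` (10 m).
#' @param slope Slope `grid_raster` (degrees, 10 m), co-registered.
#' @param n_bins Number of bins (default 120).
#' @param bounds Slope range covered by the bins (degrees).
#' @return A tibble with `bin_low`, `bin_high`, `bin_mid` (geometric
#'   midpoint), `mean_intensity`, `se`, `n`.
#' @export
intensity_by_slope <- function(intensity_r, slope, n_bins = 120,
                               bounds = c(0.01, 10)) {
  check_coregistered(intensity_r, slope, "intensity and slope")
  i <- as.vector(as_plain_matrix(intensity_r))
  s <- as.vector(as_plain_matrix(slope))
  ok <- !is.na(i) & !is.na(s)
  if (!any(ok)) {
    abort_tm("All cells are masked; nothing to bin.", "insufficient_data")
  }
  i <- i[ok]; s <- s[ok]
  edges <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_bins + 1L))
  bin <- findInterval(s, edges, rightmost.closed = TRUE)
  inside <- bin >= 1L & bin <= n_bins
  i <- i[inside]; bin <- bin[inside]
  n <- tabulate(bin, nbins = n_bins)
  s1 <- vapply(seq_len(n_bins), function(b) sum(i[bin == b]), numeric(1))
  s2 <- vapply(seq_len(n_bins), function(b) sum(i[bin == b]^2), numeric(1))
  mean_i <- ifelse(n > 0, s1 / n, NA_real_)
  sd_i <- ifelse(n > 1, sqrt(pmax(s2 - s1^2 / pmax(n, 1), 0) / (n - 1)),
                 NA_real_)
  tibble::tibble(
    bin_low = edges[seq_len(n_bins)],
    bin_high = edges[-1L],
    bin_mid = sqrt(edges[seq_len(n_bins)] * edges[-1L]),
    mean_intensity = mean_i,
    se = sd_i / sqrt(pmax(n, 1)),
    n = n
  )
}

#' Binned vegetation-establishment probability surface
#'
#' The establishment analysis: every bare, fully observed 10 m cell of
#' every campaign pair is binned by (1) micro-topography intensity (85
#' linear bins between 0 and the pooled 99.5th percentile) and (2)
#' percent skipped tidal inundations (101 unit-width bins centred on
#' 0..100), and the probability of new establishment per bin is the
#' proportion of at-risk cells that became newly vegetated. Pairs are
#' pooled by summing counts before dividing (an unweighted mean of
#' per-pair proportions is available as `mode = "average"`); bins with
#' fewer than `n_min` cells are missing, not zero.
#'
#' @param pairs A list; each element a list with components `veg_early`,
#'   `veg_late` (logical `grid_raster`s), `exposure` and `intensity`
#'   (`grid_raster`s), all co-registered at the analysis resolution.
#' @param intensity_breaks Optional intensity bin edges (length 86);
#'   default linear between 0 and the pooled 99.5th percentile.
#' @param skipped_breaks Optional skipped-percent bin edges (length 102).
#' @param n_min Minimum cells per reported bin (default 30).
#' @param mode `"pool"` (sum counts, then divide) or `"average"`
#'   (unweighted mean of per-pair proportions).
#' @return An `establishment_array`; `tidy()` gives the long format with
#'   under-populated bins absent, `autoplot()` the probability surface.
#' @export
establishment_array <- function(pairs, intensity_breaks = NULL,
                                skipped_breaks = NULL, n_min = 30,
                                mode = c("pool", "average")) {
  mode <- match.arg(mode)
  if (length(pairs) == 0L) {
    abort_tm("Need at least one campaign pair.", "invalid_argument")
  }
  for (p in pairs) {
    check_coregistered(p$veg_early, p$veg_late, "vegetation masks")
    check_coregistered(p$veg_early, p$exposure, "mask and exposure")
    check_coregistered(p$veg_early, p$intensity, "mask and intensity")
  }
  if (is.null(intensity_breaks)) {
    pooled <- unlist(purrr::map(pairs, function(p) {
      v <- as.vector(as_plain_matrix(p$intensity))
      v[!is.na(v)]
    }))
    q <- stats::quantile(pooled, 0.995, names = FALSE)
    if (!is.finite(q) || q <= 0) q <- max(pooled, 1e-6)
    intensity_breaks <- seq(0, q, length.out = 86L)
  }
  if (is.null(skipped_breaks)) skipped_breaks <- seq(-0.5, 100.5, by = 1)
  n_int <- length(intensity_breaks) - 1L
  n_sk <- length(skipped_breaks) - 1L

  n_mat <- matrix(0, n_int, n_sk)
  k_mat <- matrix(0, n_int, n_sk)
  p_sum <- matrix(0, n_int, n_sk)
  p_cnt <- matrix(0, n_int, n_sk)

  for (p in pairs) {
    nv <- new_establishment(p$veg_early, p$veg_late)
    early <- as_plain_matrix(p$veg_early)
    sk <- as.vector(as_plain_matrix(p$exposure))
    it <- as.vector(as_plain_matrix(p$intensity))
    newly <- as.vector(as_plain_matrix(nv))
    at_risk <- !is.na(newly) & !is.na(sk) & !is.na(it) &
      !as.vector(early) %in% TRUE
    sk <- sk[at_risk]; it <- it[at_risk]; newly <- newly[at_risk]
    bi <- pmin(pmax(findInterval(it, intensity_breaks,
                                 rightmost.closed = TRUE), 1L), n_int)
    bs <- findInterval(sk, skipped_breaks, rightmost.closed = TRUE)
    inside <- bs >= 1L & bs <= n_sk
    bi <- bi[inside]; bs <- bs[inside]; newly <- newly[inside]
    idx <- (bs - 1L) * n_int + bi
    np <- matrix(tabulate(idx, nbins = n_int * n_sk), n_int, n_sk)
    kp <- matrix(tabulate(idx[newly], nbins = n_int * n_sk), n_int, n_sk)
    n_mat <- n_mat + np
    k_mat <- k_mat + kp
    has <- np > 0
    p_sum[has] <- p_sum[has] + kp[has] / np[has]
    p_cnt <- p_cnt + has
  }

  prob <- if (mode == "pool") {
    ifelse(n_mat >= n_min, k_mat / pmax(n_mat, 1), NA_real_)
  } else {
    ifelse(n_mat >= n_min & p_cnt > 0, p_sum / pmax(p_cnt, 1), NA_real_)
  }
  structure(list(n = n_mat, k = k_mat, p = prob,
                 intensity_breaks = intensity_breaks,
                 skipped_breaks = skipped_breaks,
                 n_min = n_min, mode = mode, n_pairs = length(pairs)),
            class = "establishment_array")
}

#' @export
print.establishment_array <- function(x, ...) {
  cat(sprintf(paste0("<establishment_array %d x %d> %d pair(s), %d",
                     " populated bin(s) (n >= %d), mode: %s\n"),
              nrow(x$n), ncol(x$n), x$n_pairs, sum(!is.na(x$p)), x$n_min,
              x$mode))
  invisible(x)
}

#' @export
tidy.establishment_array <- function(x, ...) {
  n_int <- nrow(x$n); n_sk <- ncol(x$n)
  out <- tibble::tibble(
    intensity_low = rep(x$intensity_breaks[seq_len(n_int)], times = n_sk),
    intensity_high = rep(x$intensity_breaks[-1L], times = n_sk),
    skipped_low = rep(x$skipped_breaks[seq_len(n_sk)], each = n_int),
    skipped_high = rep(x$skipped_breaks[-1L], each = n_int),
    n = as.vector(x$n),
    k = as.vector(x$k),
    p = as.vector(x$p)
  )
  dplyr::filter(out, .data$n >= x$n_min)
}

#' @export
autoplot.establishment_array <- function(object, ...) {
  df <- tidy.establishment_array(object)
  df$skipped_mid <- (df$skipped_low + df$skipped_high) / 2
  df$intensity_mid <- (df$intensity_low + df$intensity_high) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$skipped_mid,
                                   y = .data$intensity_mid,
                                   fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "skipped tidal inundations (%)",
                  y = "micro-topography intensity (SD NIR)",
                  fill = "P(establish)")
}

#' Export an establishment array in long CSV format
#'
#' @param x An `establishment_array`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_establishment_csv <- function(x, path) {
  readr::write_csv(tidy.establishment_array(x), path)
  invisible(path)
}

#' Composite early-indicator report for a flat unit
#'
#' Evaluates, year by year, the three diagnostics of an upper flat
#' approaching the transition to marsh: (a) part of the unit sits above
#' neap high water (mean percent skipped > 0); (b) the unit is accreting
#' (positive elevation trend whose confidence interval excludes zero,
#' over at least 3 years); (c) the mean 10 m slope is below the low-slope
#' boundary at which micro-topographic patterning appears (default 0.3
#' degrees), or is declining toward it (negative slope trend with the
#' interval excluding zero). A year is flagged "approaching transition"
#' when all three hold.
#'
#' @param dem_series Named list (by year) of elevation `grid_raster`s at
#'   the analysis resolution.
#' @param exposure_series Named list (by year) of percent-skipped
#'   `grid_raster`s.
#' @param slope_series Optional named list of slope `grid_raster`s;
#'   computed from `dem_series` when omitted.
#' @param slope_threshold Low-slope boundary (degrees), default 0.3.
#' @return An `indicator_report` tibble, one row per year with all
#'   diagnostics and the `flagged` decision; the first flagged year is in
#'   the `first_flag_year` attribute (`NA` when never flagged).
#' @export
early_indicator_report <- function(dem_series, exposure_series,
                                   slope_series = NULL,
                                   slope_threshold = 0.3) {
  years <- as.numeric(names(dem_series))
  if (length(years) < 3L || any(is.na(years))) {
    abort_tm("Need a named list of at least 3 years of DEMs.",
             "invalid_argument")
  }
  if (is.null(slope_series)) {
    slope_series <- purrr::map(dem_series, slope_deg)
  }
  mean_of <- function(r) mean(as_plain_matrix(r), na.rm = TRUE)
  mean_elev <- vapply(dem_series, mean_of, numeric(1))
  mean_sk <- vapply(exposure_series, mean_of, numeric(1))
  mean_sl <- vapply(slope_series, mean_of, numeric(1))

  rows <- purrr::map_dfr(seq_along(years), function(i) {
    if (i >= 3L) {
      acc <- annual_trend(years[1:i], mean_elev[1:i])
      slt <- annual_trend(years[1:i], mean_sl[1:i])
      accreting <- acc$slope > 0 && !is.na(acc$ci_low) && acc$ci_low > 0
      flattening <- mean_sl[i] < slope_threshold ||
        (slt$slope < 0 && !is.na(slt$ci_high) && slt$ci_high < 0)
      tibble::tibble(
        year = years[i], mean_elevation_cm = mean_elev[i],
        mean_skipped_pct = mean_sk[i], mean_slope_deg = mean_sl[i],
        accretion_cm_yr = acc$slope, accretion_ci_low = acc$ci_low,
        slope_trend_deg_yr = slt$slope,
        above_nhwl = mean_sk[i] > 0, accreting = accreting,
        low_slope = flattening,
        flagged = mean_sk[i] > 0 && accreting && flattening
      )
    } else {
      tibble::tibble(
        year = years[i], mean_elevation_cm = mean_elev[i],
        mean_skipped_pct = mean_sk[i], mean_slope_deg = mean_sl[i],
        accretion_cm_yr = NA_real_, accretion_ci_low = NA_real_,
        slope_trend_deg_yr = NA_real_,
        above_nhwl = mean_sk[i] > 0, accreting = FALSE, low_slope = FALSE,
        flagged = FALSE
      )
    }
  })
  first_flag <- if (any(rows$flagged)) min(rows$year[rows$flagged]) else NA
  attr(rows, "first_flag_year") <- first_flag
  attr(rows, "slope_threshold") <- slope_threshold
  class(rows) <- c("indicator_report", class(rows))
  rows
}

#' Crop a grid raster to a row/column window
#'
#' Used to carve analysis units (e.g. the upper flat) out of a scene.
#'
#' @param r A `grid_raster`.
#' @param rows,cols Integer index vectors (contiguous ranges).
#' @return The cropped `grid_raster` with an adjusted origin.
#' @export
crop_grid <- function(r, rows, cols) {
  cs <- cell_size(r)
  o <- grid_origin(r)
  m <- as_plain_matrix(r)[rows, cols, drop = FALSE]
  grid_raster(m, cell_size = cs,
              origin = c(o[1] + (min(cols) - 1) * cs,
                         o[2] - (min(rows) - 1) * cs),
              kind = grid_kind(r))
}
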