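#' Configuration for the synthetic estuary generator
#'
#' Bundles every parameter of the synthetic estuary: grid geometry, the
#' accreting convex cross-shore profile, ridge-runnel pattern texture
#' (vertical relief capped at 10 cm, the observed envelope of tidal-flat
#' micro-topography), tidal constituents with along-estuary amplification,
#' orthophoto reflectance coupling, and the logistic vegetation-
#' establishment model. Defaults describe a macro-tidal NW-European
#' estuary: M2 amplitude 150 cm and S2 50 cm give a 4 m spring and 2 m
#' neap range, and accretion of 2 cm per year sits in the 1-3 cm per year
#' band observed on rising upper flats.
#'
#' @param rows,cols Grid shape of the native-resolution scene.
#' @param cell_size Cell edge length (m).
#' @param years Strictly increasing integer years.
#' @param accretion_cm_yr Uniform accretion on the upper flat (cm per
#'   year, >= 0).
#' @param channel_depth_cm,flat_height_cm,convexity Cross-shore profile:
#'   elevation falls from `flat_height_cm` at the landward edge to
#'   `channel_depth_cm` at the channel as `u^convexity` (`u` the relative
#'   cross-shore coordinate); `convexity > 1` gives the flat anterior
#'   section high in the tidal frame.
#' @param pattern_wavelength_m,pattern_relief_cm,pattern_slope_ceiling_deg
#'   Ridge-runnel texture: quasi-periodic wavelength (m), peak-to-trough
#'   relief (cm, at most 10), and the slope ceiling (degrees) below which
#'   the texture is planted.
#' @param n_creeks,creek_depth_cm Number of incised tidal creeks and their
#'   centre-line incision depth (cm); walls are steeper than 3 degrees.
#' @param mega_wavelength_m,mega_relief_cm Mega-ripple texture added below
#'   the zero-exposure elevation.
#' @param m2_cm,s2_cm M2 (12.42 h) and S2 (12.00 h) amplitudes (cm, > 0);
#'   their superposition carries the spring-neap envelope.
#' @param amplification Per-station amplification factors (same length as
#'   the station positions), or `NULL` for a linear 1 to 1.1 increase
#'   along the axis.
#' @param tide_noise_cm Gaussian noise SD on the gauge record (cm).
#' @param tide_days,tide_dt_min Record duration (days) and sampling
#'   interval (minutes).
#' @param nir_base,nir_wet_gain,nir_relief_gain,nir_noise NIR reflectance
#'   model: base level, darkening with wetness (1 - skipped/100), gain on
#'   the local elevation anomaly (per cm; runnels pool water and darken),
#'   and sensor noise SD.
#' @param ndvi_sediment,ndvi_vegetation,ndvi_sd Modes and common SD of the
#'   bimodal NDVI mixture painted into the bands.
#' @param veg_intercept,veg_coef_skipped,veg_coef_intensity Logistic
#'   establishment model: `p = plogis(intercept + a * skipped_pct +
#'   b * intensity)`, forced to zero where no inundations are skipped.
#' @param seed Root integer seed; every stage derives a named substream.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(rows = 400, cols = 400, cell_size = 1,
                         years = 2004:2010, accretion_cm_yr = 2,
                         channel_depth_cm = -150, flat_height_cm = 170,
                         convexity = 3,
                         pattern_wavelength_m = 3, pattern_relief_cm = 6,
                         pattern_slope_ceiling_deg = 0.3,
                         n_creeks = 2, creek_depth_cm = 60,
                         mega_wavelength_m = 25, mega_relief_cm = 15,
                         m2_cm = 150, s2_cm = 50, amplification = NULL,
                         tide_noise_cm = 2, tide_days = 30,
                         tide_dt_min = 10,
                         nir_base = 0.45, nir_wet_gain = 0.10,
                         nir_relief_gain = 0.015, nir_noise = 0.005,
                         ndvi_sediment = 0.10, ndvi_vegetation = 0.50,
                         ndvi_sd = 0.05,
                         veg_intercept = -8, veg_coef_skipped = 0.06,
                         veg_coef_intensity = 40,
                         seed = 1) {
  cfg <- as.list(environment())
  if (pattern_relief_cm > 10) {
    abort_tm("Pattern relief above 10 cm exceeds the micro-topography envelope.",
             "invalid_config")
  }
  if (accretion_cm_yr < 0) {
    abort_tm("Accretion rate must be >= 0.", "invalid_config")
  }
  if (m2_cm <= 0 || s2_cm <= 0) {
    abort_tm("Tidal amplitudes must be positive.", "invalid_config")
  }
  if (length(years) > 1L && any(diff(years) <= 0)) {
    abort_tm("`years` must be strictly increasing.", "invalid_config")
  }
  if (tide_dt_min <= 0) {
    abort_tm("Sampling interval must be positive.", "invalid_config")
  }
  if (veg_coef_skipped < 0 || veg_coef_intensity < 0) {
    abort_tm("Vegetation driver coefficients must be >= 0.", "invalid_config")
  }
  structure(cfg, class = "synth_config")
}

#' Read and write generator configurations as YAML
#'
#' @param path YAML file path.
#' @param config A [synth_config()].
#' @return `read_synth_config()` returns a validated `synth_config`;
#'   `write_synth_config()` returns `path` invisibly.
#' @export
read_synth_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(synth_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort_tm(paste("Unknown config fields:", paste(unknown, collapse = ", ")),
             "invalid_config")
  }
  do.call(synth_config, vals)
}

#' @rdname read_synth_config
#' @export
write_synth_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# neap high water proxy: lowest high tide of a noise-free record at unit
# amplification; used to place mega-ripples during DEM generation
nhwl_proxy <- function(config) config$m2_cm - config$s2_cm

#' Synthetic multi-station tide records
#'
#' M2 + S2 superposition (periods 12.42 h and 12.00 h, equal phase at
#' t = 0 so the record opens at spring tide), scaled by each station's
#' amplification factor, plus seeded Gaussian gauge noise. The two
#' constituents beat with a 14.77-day spring-neap envelope.
#'
#' @param config A [synth_config()].
#' @param station_positions Along-axis station coordinates (m).
#' @return A list of [water_level_series()], one per station.
#' @export
gen_tide_series <- function(config, station_positions = c(0, 200, 400)) {
  if (config$tide_dt_min <= 0) {
    abort_tm("Sampling interval must be positive.", "invalid_config")
  }
  amp <- config$amplification
  if (is.null(amp)) {
    rng <- range(station_positions)
    span <- if (diff(rng) > 0) diff(rng) else 1
    amp <- 1 + 0.1 * (station_positions - rng[1]) / span
  }
  if (length(amp) != length(station_positions)) {
    abort_tm("`amplification` must match the number of stations.",
             "invalid_config")
  }
  t_h <- seq(0, config$tide_days * 24, by = config$tide_dt_min / 60)
  purrr::map(seq_along(station_positions), function(i) {
    old <- .Random.seed_exists()
    set.seed(derive_seed(config$seed, paste0("tide-", i)))
    noise <- rnorm(length(t_h), 0, config$tide_noise_cm)
    .restore_seed(old)
    lvl <- amp[i] * (config$m2_cm * cos(2 * pi * t_h / 12.42) +
                       config$s2_cm * cos(2 * pi * t_h / 12.00)) + noise
    water_level_series(t_h, lvl, station = sprintf("S%02d", i),
                       position_m = station_positions[i])
  })
}

# valid-aware box blur at native resolution (square window of f cells)
box_blur <- function(m, f) {
  valid <- !is.na(m)
  mz <- ifelse(valid, m, 0)
  half_lo <- (f - 1L) %/% 2L
  half_hi <- f - 1L - half_lo
  box <- function(x) {
    nr <- nrow(x); nc <- ncol(x)
    cum <- t(apply(apply(x, 2L, cumsum), 1L, cumsum))
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
  out <- ifelse(n > 0, s1 / n, NA_real_)
  out[!valid] <- NA
  out
}

# repeat each cell of a coarse matrix f x f times
upsample_blocks <- function(m, f, rows, cols) {
  big <- m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f),
           drop = FALSE]
  big[seq_len(rows), seq_len(cols), drop = FALSE]
}

#' Synthetic accreting DEM time series with ground truth
#'
#' Builds one elevation raster per year: a convex cross-shore profile
#' (monotone from the high flat at the top rows to the channel at the
#' bottom), uniform accretion on the upper flat, quasi-periodic
#' ridge-runnel texture planted only where the smooth (pre-texture)
#' surface is gentler than the pattern slope ceiling and above neap high
#' water, incised creeks with walls steeper than 3 degrees, and
#' mega-ripples below the zero-exposure elevation. The texture fields are
#' static; only accretion moves the surface between years.
#'
#' @param config A [synth_config()].
#' @return A list with `dems` (named list of elevation `grid_raster`s, one
#'   per year) and `truth` (pattern, creek, mega-ripple and flat masks,
#'   the pre-texture slope, and the neap-high-water proxy used).
#' @export
gen_dem_series <- function(config) {
  rows <- config$rows; cols <- config$cols; cs <- config$cell_size
  u <- (seq_len(rows) - 1) / (rows - 1)
  base_profile <- config$flat_height_cm -
    (config$flat_height_cm - config$channel_depth_cm) * u^config$convexity
  base <- matrix(rep(base_profile, cols), rows, cols)
  nhwl <- nhwl_proxy(config)

  old <- .Random.seed_exists()
  set.seed(derive_seed(config$seed, "dem"))

  # pre-texture slope governs where ridge-runnel texture may appear
  base_grid <- grid_raster(base, cell_size = cs, kind = "elevation")
  pre_slope <- slope_deg(base_grid)
  slope_ok <- as_plain_matrix(pre_slope) < config$pattern_slope_ceiling_deg
  slope_ok[is.na(slope_ok)] <- FALSE

  # creeks: meandering cross-shore incisions
  creek_incision <- matrix(0, rows, cols)
  if (config$n_creeks > 0) {
    for (k in seq_len(config$n_creeks)) {
      c0 <- runif(1, 0.15, 0.85) * cols
      meander <- cumsum(rnorm(rows, 0, 0.4))
      meander <- stats::filter(meander, rep(1 / 15, 15), circular = TRUE)
      centre <- c0 + as.numeric(meander)
      w <- 1.0 / cs # creek half-width ~1 m: relief dies out within ~3 m,
      # so every tile carrying creek relief also carries a > 3 degree wall
      for (r in seq_len(rows)) {
        d2 <- (seq_len(cols) - centre[r])^2
        creek_incision[r, ] <- pmax(creek_incision[r, ],
                                    config$creek_depth_cm *
                                      exp(-d2 / (2 * w^2)))
      }
    }
  }
  creek_mask <- creek_incision > 0.1 * config$creek_depth_cm

  # ridge-runnel texture: anisotropic sinusoid modulated by fractal noise
  y_m <- matrix(rep(seq_len(rows) * cs, cols), rows, cols)
  mod_noise <- fractal_surface(max(rows, cols), sd = 1, roughness = 1.5,
                               seed = derive_seed(config$seed, "pattern-mod"))
  mod_noise <- mod_noise[seq_len(rows), seq_len(cols), drop = FALSE]
  mod01 <- (mod_noise - min(mod_noise)) / (max(mod_noise) - min(mod_noise))
  # ridge phase drifts only over tens of metres so the quasi-periodic
  # texture does not leak into the 10 m slope product
  win <- max(3L, as.integer(round(25 / cs)))
  phase_row <- 2 * pi * as.numeric(
    stats::filter(mod01[1, ], rep(1 / win, win), circular = TRUE))
  phase <- matrix(rep(phase_row, each = rows), rows, cols)
  pattern_field <- (config$pattern_relief_cm / 2) *
    sin(2 * pi * y_m / config$pattern_wavelength_m + phase) *
    (0.6 + 0.4 * mod01)
  total_acc <- config$accretion_cm_yr *
    (max(config$years) - min(config$years))
  # texture precedes the exposure threshold: plant it on every gentle cell
  # that reaches the neap-high-water zone within the simulated period
  pattern_mask <- slope_ok & base >= (nhwl - total_acc) & !creek_mask
  # patterns are strongest on the flattest beds and weaken toward the
  # slope ceiling, and they fade toward the zone edge instead of stopping
  # abruptly, so the texture adds no artificial step to the coarse slope
  ps <- as_plain_matrix(pre_slope)
  ps[is.na(ps)] <- config$pattern_slope_ceiling_deg
  slope_fade <- sqrt(pmax(0, 1 - ps / config$pattern_slope_ceiling_deg))
  edge_fade <- box_blur(pattern_mask * 1, max(3L, as.integer(round(15 / cs))))
  pattern_field <- pattern_field * edge_fade * slope_fade
  pattern_field[!pattern_mask] <- 0

  # mega-ripples in the zone that stays below neap high water throughout
  mega_mask <- base < (nhwl - total_acc - 5)
  mega_field <- (config$mega_relief_cm / 2) *
    sin(2 * pi * y_m / config$mega_wavelength_m + 2 * phase)
  mega_field[!mega_mask] <- 0

  .restore_seed(old)

  # accretion weight: full on the upper flat, tapering to zero down-slope
  flat_mask <- base >= 0
  taper <- pmin(1, pmax(0, (base - (-50)) / 50))
  texture <- pattern_field + mega_field - creek_incision

  dems <- purrr::map(config$years, function(yr) {
    z <- base + config$accretion_cm_yr * (yr - config$years[1]) * taper +
      texture
    grid_raster(z, cell_size = cs, kind = "elevation")
  })
  names(dems) <- as.character(config$years)

  list(
    dems = dems,
    truth = list(
      pattern_mask = grid_raster(pattern_mask, cell_size = cs, kind = "mask"),
      creek_mask = grid_raster(creek_mask, cell_size = cs, kind = "mask"),
      mega_mask = grid_raster(mega_mask, cell_size = cs, kind = "mask"),
      flat_mask = grid_raster(flat_mask, cell_size = cs, kind = "mask"),
      pre_texture_slope = pre_slope,
      nhwl_proxy_cm = nhwl,
      base = base_grid
    )
  )
}

#' Synthetic false-colour orthophoto of a scene
#'
#' NIR reflectance is a base level, darkened where the flat is wetter
#' (lower percent of skipped inundations), brightened and darkened with
#' the local small-scale elevation anomaly (ridges drain and brighten;
#' runnels pool and darken), plus Gaussian sensor noise. Vegetated cells
#' receive an NIR/Red combination whose NDVI is drawn from the vegetation
#' mode of a bimodal mixture, well above the sediment mode; bare cells
#' draw from the sediment mode. Within-window NIR variability therefore
#' rises with within-window relief by construction.
#'
#' @param dem Elevation `grid_raster` (native resolution).
#' @param exposure Percent-skipped `grid_raster`, co-registered with `dem`.
#' @param veg_mask Logical vegetation `grid_raster`, co-registered.
#' @param config A [synth_config()].
#' @param year Campaign year label.
#' @param seed Seed for the sensor noise and NDVI draws; defaults to a
#'   substream of `config$seed` keyed by `year`.
#' @return An [ortho_image()] with NIR, Red and Green bands.
#' @export
gen_ortho <- function(dem, exposure, veg_mask, config, year = NA_integer_,
                      seed = NULL) {
  check_coregistered(dem, exposure, "DEM and exposure")
  check_coregistered(dem, veg_mask, "DEM and vegetation mask")
  if (is.null(seed)) {
    seed <- derive_seed(config$seed, paste0("ortho-", year))
  }
  z <- as_plain_matrix(dem)
  sk <- as_plain_matrix(exposure)
  veg <- as_plain_matrix(veg_mask)
  veg[is.na(veg)] <- FALSE
  blur_win <- max(3L, as.integer(round(2 * config$pattern_wavelength_m /
                                         config$cell_size)))
  anomaly <- z - box_blur(z, blur_win)

  old <- .Random.seed_exists()
  set.seed(seed)
  noise <- matrix(rnorm(length(z), 0, config$nir_noise), nrow(z))
  ndvi_t <- matrix(rnorm(length(z), config$ndvi_sediment, config$ndvi_sd),
                   nrow(z))
  veg_draw <- matrix(rnorm(length(z), config$ndvi_vegetation,
                           config$ndvi_sd), nrow(z))
  .restore_seed(old)

  ndvi_t <- pmin(ndvi_t, config$ndvi_sediment + 3.9 * config$ndvi_sd)
  veg_draw <- pmax(pmin(veg_draw, 0.95),
                   config$ndvi_sediment + 4 * config$ndvi_sd)
  ndvi_t[veg] <- veg_draw[veg]

  nir <- config$nir_base -
    config$nir_wet_gain * (1 - sk / 100) +
    config$nir_relief_gain * anomaly +
    noise
  nir <- pmax(nir, 0.02)
  red <- nir * (1 - ndvi_t) / (1 + ndvi_t)
  green <- 0.3 + 0.3 * (nir - config$nir_base)

  mk <- function(m) grid_like(dem, m, kind = "reflectance")
  ortho_image(mk(nir), mk(red), mk(green), year = year)
}

#' Stochastic vegetation establishment on the synthetic flat
#'
#' Per interval, each bare cell establishes vegetation with probability
#' `plogis(intercept + a * skipped_pct + b * intensity)`, forced to zero
#' wherever no tidal inundations are skipped (no establishment below neap
#' high water). Established vegetation persists.
#'
#' @param exposure Percent-skipped `grid_raster` (values in `[0, 100]`).
#' @param intensity_r Micro-topography intensity `grid_raster`,
#'   co-registered with `exposure`.
#' @param config A [synth_config()].
#' @param n_intervals Number of establishment intervals (default: one).
#' @param init Initial vegetation mask (default: all bare).
#' @param seed Seed; defaults to a substream of `config$seed`.
#' @return A list with `masks` (length `n_intervals + 1`, the first being
#'   the initial state) and `p_true` (the establishment-probability
#'   `grid_raster`).
#' @export
evolve_vegetation <- function(exposure, intensity_r, config,
                              n_intervals = 1L, init = NULL, seed = NULL) {
  check_coregistered(exposure, intensity_r, "exposure and intensity")
  sk <- as_plain_matrix(exposure)
  if (any(sk < 0 | sk > 100, na.rm = TRUE)) {
    abort_tm("Exposure must lie in [0, 100].", "invalid_config")
  }
  inten <- as_plain_matrix(intensity_r)
  p <- plogis(config$veg_intercept + config$veg_coef_skipped * sk +
                config$veg_coef_intensity * inten)
  p[!is.na(sk) & sk == 0] <- 0
  p[is.na(sk) | is.na(inten)] <- NA
  if (is.null(seed)) seed <- derive_seed(config$seed, "veg")
  veg <- if (is.null(init)) {
    matrix(FALSE, nrow(sk), ncol(sk))
  } else as_plain_matrix(init)
  masks <- vector("list", n_intervals + 1L)
  masks[[1L]] <- grid_like(exposure, veg, kind = "mask")
  old <- .Random.seed_exists()
  set.seed(seed)
  for (i in seq_len(n_intervals)) {
    draw <- matrix(runif(length(p)), nrow(p))
    newly <- !veg & !is.na(p) & draw < p
    veg <- veg | newly
    masks[[i + 1L]] <- grid_like(exposure, veg, kind = "mask")
  }
  .restore_seed(old)
  list(masks = masks, p_true = grid_like(exposure, p, kind = "other"))
}

#' Generate a complete synthetic estuary scene
#'
#' Orchestrates the generator: tide records and station exposure curves,
#' the accreting DEM series, per-year exposure rasters at native and 10 m
#' resolution, orthophotos whose NIR texture follows the bed relief,
#' 10 m micro-topography intensity, and stochastic vegetation dynamics
#' driven by the same 10 m exposure and intensity rasters that any
#' downstream analysis sees. Every random draw derives from the config
#' seed, so identical configs give bit-identical scenes.
#'
#' @param config A [synth_config()].
#' @param station_positions Along-axis tide-gauge positions (m); default:
#'   both ends and the middle of the scene.
#' @return A `synth_scene` list: `config`, `series`, `curves`, `dems`,
#'   `dem10`, `exposure`, `exposure10`, `slope10`, `slope_fine`, `orthos`,
#'   `intensity10`, `veg10` (per-year 10 m masks), `p_true` (per-interval
#'   probability rasters) and `truth` from [gen_dem_series()].
#' @export
synth_estuary <- function(config, station_positions = NULL) {
  cs <- config$cell_size
  width_m <- config$cols * cs
  if (is.null(station_positions)) {
    station_positions <- c(0, width_m / 2, width_m)
  }
  series <- gen_tide_series(config, station_positions)
  curves <- purrr::map(series, exposure_curve)

  dem_out <- gen_dem_series(config)
  dems <- dem_out$dems
  years <- config$years
  n_years <- length(years)

  fine_cell <- if (cs < 2) 2 else cs
  dem10 <- purrr::map(dems, block_resample, target_cell = 10,
                      aggregator = "mean")
  exposure <- purrr::map(dems, exposure_raster, curves = curves)
  exposure10 <- purrr::map(dem10, exposure_raster, curves = curves)
  slope10 <- purrr::map(dem10, slope_deg)
  slope_fine <- purrr::map(dems, function(d) {
    slope_deg(if (cell_size(d) < fine_cell) {
      block_resample(d, fine_cell, "mean")
    } else d)
  })

  f10 <- as.integer(round(10 / cs))
  orthos <- vector("list", n_years)
  intensity10 <- vector("list", n_years)
  veg10 <- vector("list", n_years)
  p_true <- vector("list", n_years - 1L)
  veg10_cur <- grid_like(dem10[[1]],
                         matrix(FALSE, nrow(dem10[[1]]), ncol(dem10[[1]])),
                         kind = "mask")
  for (i in seq_len(n_years)) {
    veg_native <- grid_like(dems[[i]],
                            upsample_blocks(as_plain_matrix(veg10_cur), f10,
                                            config$rows, config$cols),
                            kind = "mask")
    orthos[[i]] <- gen_ortho(dems[[i]], exposure[[i]], veg_native, config,
                             year = years[i])
    intensity10[[i]] <- intensity(orthos[[i]], window = 10)
    veg10[[i]] <- veg10_cur
    if (i < n_years) {
      ev <- evolve_vegetation(exposure10[[i]], intensity10[[i]], config,
                              n_intervals = 1L, init = veg10_cur,
                              seed = derive_seed(config$seed,
                                                 paste0("veg-", years[i])))
      p_true[[i]] <- ev$p_true
      veg10_cur <- ev$masks[[2]]
    }
  }
  names(orthos) <- names(intensity10) <- names(veg10) <- as.character(years)

  structure(list(
    config = config, series = series, curves = curves,
    dems = dems, dem10 = dem10,
    exposure = exposure, exposure10 = exposure10,
    slope10 = slope10, slope_fine = slope_fine,
    orthos = orthos, intensity10 = intensity10,
    veg10 = veg10, p_true = p_true,
    truth = dem_out$truth
  ), class = "synth_scene")
}

#' @export
print.synth_scene <- function(x, ...) {
  cat(sprintf("<synth_scene> %d x %d cells at %g m, years %s-%s, seed %d\n",
              x$config$rows, x$config$cols, x$config$cell_size,
              head(x$config$years, 1), tail(x$config$years, 1),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' Rasters go out as ESRI ASCII grids, tide records as a CSV water-level
#' table, and the ground truth (masks plus scalar truth values) as ASCII
#' grids with a JSON sidecar, so a scene can be consumed by the pipeline
#' like any external dataset.
#'
#' @param scene A [synth_estuary()] scene.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  years <- as.character(scene$config$years)
  for (y in years) {
    write_grid_asc(scene$dems[[y]], file.path(dir, paste0("dem_", y, ".asc")))
    write_grid_asc(scene$orthos[[y]]$nir,
                   file.path(dir, paste0("nir_", y, ".asc")))
    write_grid_asc(scene$orthos[[y]]$red,
                   file.path(dir, paste0("red_", y, ".asc")))
    write_grid_asc(scene$veg10[[y]], file.path(dir, paste0("veg10_", y,
                                                           ".asc")))
  }
  write_water_levels(scene$series, file.path(dir, "water_levels.csv"))
  write_grid_asc(scene$truth$pattern_mask,
                 file.path(dir, "truth_pattern_mask.asc"))
  write_grid_asc(scene$truth$creek_mask,
                 file.path(dir, "truth_creek_mask.asc"))
  jsonlite::write_json(
    list(nhwl_proxy_cm = scene$truth$nhwl_proxy_cm,
         years = scene$config$years, seed = scene$config$seed,
         synthetic = TRUE),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  write_synth_config(scene$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
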