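test_that("config validation enforces the stated envelopes", {
  expect_error(synth_config(pattern_relief_cm = 12),
               class = "tidalmarsh_invalid_config")
  expect_error(synth_config(accretion_cm_yr = -1),
               class = "tidalmarsh_invalid_config")
  expect_error(synth_config(m2_cm = 0),
               class = "tidalmarsh_invalid_config")
  expect_error(synth_config(years = c(2005, 2004)),
               class = "tidalmarsh_invalid_config")
  expect_error(synth_config(tide_dt_min = 0),
               class = "tidalmarsh_invalid_config")
})

test_that("config YAML round trip reproduces the config", {
  cfg <- small_synth_config(seed = 5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synth_config(cfg, path)
  cfg2 <- read_synth_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("tide generator: amplitudes, peak cadence, superposition", {
  cfg <- small_synth_config()
  # pure M2: max within one sample step of the amplitude
  cfg_m2 <- small_synth_config(s2_cm = 1e-9, tide_noise_cm = 0,
                               m2_cm = 200)
  ser <- gen_tide_series(cfg_m2, c(0, 100))
  expect_equal(max(ser[[1]]$level_cm), 200, tolerance = 0.1)

  # M2 + S2, equal phase at t = 0: constructive superposition
  ser2 <- gen_tide_series(small_synth_config(tide_noise_cm = 0), c(0))
  expect_gt(max(ser2[[1]]$level_cm), 150)
  # spring-neap envelope: neap high tides well below spring high tides
  peaks <- extract_high_tides(ser2[[1]])
  expect_gt(max(peaks$level_cm) - min(peaks$level_cm), 50)

  # amplification scales stations along the axis
  ser3 <- gen_tide_series(small_synth_config(tide_noise_cm = 0),
                          c(0, 500, 1000))
  expect_equal(max(ser3[[3]]$level_cm) / max(ser3[[1]]$level_cm), 1.1,
               tolerance = 0.01)
})

test_that("DEM series: accretion, monotone profile, pattern and creek truth", {
  cfg <- small_synth_config(accretion_cm_yr = 2)
  out <- gen_dem_series(cfg)
  expect_length(out$dems, length(cfg$years))

  flat <- as.matrix(out$truth$flat_mask)
  d1 <- as.matrix(out$dems[[1]])
  d2 <- as.matrix(out$dems[[2]])
  expect_equal(mean(d2[flat]) - mean(d1[flat]), 2, tolerance = 0.05)

  # cross-shore profile monotone from high flat to channel
  base <- as.matrix(out$truth$base)
  expect_true(all(diff(base[, 1]) <= 0))

  # planted pattern cells all satisfy the pre-texture slope ceiling
  pat <- as.matrix(out$truth$pattern_mask)
  ps <- as.matrix(out$truth$pre_texture_slope)
  expect_true(all(ps[pat] < cfg$pattern_slope_ceiling_deg, na.rm = TRUE))

  # creek walls steeper than 3 degrees at native resolution
  sl <- as.matrix(slope_deg(out$dems[[1]]))
  creek <- as.matrix(out$truth$creek_mask)
  wall <- creek & !is.na(sl)
  expect_gt(sum(wall), 50)
  expect_gte(mean(sl[wall] > 3), 0.9)
})

test_that("relief envelope: planted texture stays within 10 cm", {
  cfg <- small_synth_config(accretion_cm_yr = 0, n_creeks = 0)
  out <- gen_dem_series(cfg)
  anomaly <- as.matrix(out$dems[[1]]) - as.matrix(out$truth$base)
  pat <- as.matrix(out$truth$pattern_mask)
  expect_lte(max(anomaly[pat]) - min(anomaly[pat]), 10)
})

test_that("orthophotos couple NIR variability to relief and honour truth", {
  sc <- small_scene()
  yr <- as.character(sc$config$years[1])

  # patterned windows have strictly greater windowed SD(NIR)
  i10 <- as.matrix(sc$intensity10[[yr]])
  pat10 <- as.matrix(block_resample(sc$truth$pattern_mask, 10, "mean"))
  mega10 <- as.matrix(block_resample(sc$truth$mega_mask, 10, "mean"))
  creek10 <- as.matrix(block_resample(sc$truth$creek_mask, 10, "mean"))
  smooth <- pat10 == 0 & mega10 == 0 & creek10 == 0
  expect_gt(mean(i10[pat10 > 0.8], na.rm = TRUE),
            mean(i10[smooth], na.rm = TRUE))

  # fully vegetated scene: every NDVI above the sediment mode
  cfg <- small_synth_config()
  dem <- grid_raster(matrix(150, 40, 40), kind = "elevation")
  expos <- grid_raster(matrix(30, 40, 40), kind = "skipped")
  veg_all <- grid_raster(matrix(TRUE, 40, 40), kind = "mask")
  img <- gen_ortho(dem, expos, veg_all, cfg, year = 2004)
  nd <- as.matrix(ndvi(img))
  expect_true(all(nd > cfg$ndvi_sediment))

  # zero noise, flat bed, no vegetation: constant NIR, zero intensity
  cfg0 <- small_synth_config(nir_noise = 0)
  img0 <- gen_ortho(dem, expos,
                    grid_raster(matrix(FALSE, 40, 40), kind = "mask"),
                    cfg0, year = 2004)
  expect_true(all(as.matrix(intensity(img0)) == 0))

  expect_error(
    gen_ortho(dem, grid_raster(matrix(1, 3, 3), kind = "skipped"),
              veg_all, cfg),
    class = "tidalmarsh_coregistration")
})

test_that("vegetation dynamics follow the logistic truth", {
  cfg <- small_synth_config()
  # no establishment where no inundations are skipped
  zero <- grid_raster(matrix(0, 30, 30), kind = "skipped")
  inten <- grid_raster(matrix(0.05, 30, 30))
  ev <- evolve_vegetation(zero, inten, cfg, n_intervals = 5)
  expect_false(any(as.matrix(ev$masks[[6]])))
  expect_true(all(as.matrix(ev$p_true) == 0))

  # calibrated half-probability stratum: binomial recovery
  cfg_half <- small_synth_config(veg_intercept = 0, veg_coef_skipped = 0,
                                 veg_coef_intensity = 0)
  sk <- grid_raster(matrix(50, 100, 100), kind = "skipped")
  ev2 <- evolve_vegetation(sk, grid_raster(matrix(0, 100, 100)), cfg_half,
                           n_intervals = 1)
  frac <- mean(as.matrix(ev2$masks[[2]]))
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(frac - 0.5), 3 * se)

  # certain establishment fills the stratum in one interval
  cfg_one <- small_synth_config(veg_intercept = 50, veg_coef_skipped = 0,
                                veg_coef_intensity = 0)
  ev3 <- evolve_vegetation(sk, grid_raster(matrix(0, 100, 100)), cfg_one,
                           n_intervals = 1)
  expect_true(all(as.matrix(ev3$masks[[2]])))

  # persistence: vegetation never reverts
  ev4 <- evolve_vegetation(sk, grid_raster(matrix(0.02, 100, 100)), cfg,
                           n_intervals = 4)
  for (i in 2:5) {
    prev <- as.matrix(ev4$masks[[i - 1]])
    cur <- as.matrix(ev4$masks[[i]])
    expect_true(all(cur[prev]))
  }

  # truth monotone in both drivers
  p <- as.matrix(ev4$p_true)
  expect_true(all(p >= 0 & p <= 1))
  sk_var <- grid_raster(matrix(seq(0, 80, length.out = 900), 30, 30),
                        kind = "skipped")
  p_lo <- evolve_vegetation(sk_var, grid_raster(matrix(0.01, 30, 30)),
                            cfg)$p_true
  p_hi <- evolve_vegetation(sk_var, grid_raster(matrix(0.06, 30, 30)),
                            cfg)$p_true
  expect_true(all(as.matrix(p_hi) >= as.matrix(p_lo)))

  expect_error(
    evolve_vegetation(grid_raster(matrix(150, 3, 3), kind = "skipped"),
                      grid_raster(matrix(0, 3, 3)), cfg),
    class = "tidalmarsh_invalid_config")
})

test_that("identical config and seed give bit-identical scenes", {
  cfg <- synth_config(rows = 60, cols = 60, years = 2004:2006, seed = 99)
  a <- synth_estuary(cfg)
  b <- synth_estuary(cfg)
  expect_identical(as.matrix(a$dems[[2]]), as.matrix(b$dems[[2]]))
  expect_identical(as.matrix(a$orthos[[2]]$nir), as.matrix(b$orthos[[2]]$nir))
  expect_identical(as.matrix(a$veg10[[3]]), as.matrix(b$veg10[[3]]))
  expect_identical(a$series[[1]]$level_cm, b$series[[1]]$level_cm)
})

test_that("exposure realism: zero-exposure and >50% skipped zones both exist", {
  sc <- small_scene()
  yr <- as.character(sc$config$years[1])
  e <- as.matrix(sc$exposure[[yr]])
  expect_gt(sum(e == 0, na.rm = TRUE), 0)
  expect_gt(sum(e > 50, na.rm = TRUE), 0)
})

test_that("flats above NHWL expand as the flat accretes", {
  sc <- small_scene()
  yrs <- as.character(sc$config$years)
  first <- as.matrix(sc$exposure10[[yrs[1]]]) > 0
  last <- as.matrix(sc$exposure10[[yrs[length(yrs)]]]) > 0
  expect_true(all(last[first]))
  expect_gt(sum(last), sum(first))
})

test_that("scene export writes rasters, tide CSV and truth sidecar", {
  cfg <- synth_config(rows = 40, cols = 40, years = 2004:2005, seed = 12)
  sc <- synth_estuary(cfg)
  dir <- withr::local_tempdir()
  write_synth_scene(sc, dir)
  expect_true(file.exists(file.path(dir, "dem_2004.asc")))
  expect_true(file.exists(file.path(dir, "water_levels.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_true(isTRUE(gt$synthetic))
  dem_back <- read_grid_asc(file.path(dir, "dem_2004.asc"))
  expect_equal(as.matrix(dem_back), as.matrix(sc$dems[["2004"]]),
               tolerance = 1e-6)
})
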