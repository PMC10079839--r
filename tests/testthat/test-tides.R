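test_that("high-tide extraction counts one peak per tidal period", {
  t_h <- seq(0, 124.2, by = 1 / 6)
  s <- water_level_series(t_h, 200 * sin(2 * pi * t_h / 12.42))
  peaks <- extract_high_tides(s)
  expect_equal(nrow(peaks), 10)
  expect_equal(max(peaks$level_cm), 200, tolerance = 1e-3)

  ramp <- water_level_series(1:100, 1:100)
  expect_warning(p0 <- extract_high_tides(ramp), "maxima")
  expect_equal(nrow(p0), 0)

  expect_error(extract_high_tides(s, min_separation = 0),
               class = "tidalmarsh_invalid_argument")
  expect_error(water_level_series(c(1, 1, 2), c(0, 1, 2)),
               class = "tidalmarsh_invalid_argument")
})

test_that("M2+S2 peaks equal the brute-force neighbour-scan oracle", {
  for (seed in 1:5) {
    s <- make_m2s2_series(days = 20, noise = 3, seed = seed)
    got <- extract_high_tides(s)
    idx <- oracle_high_tides(s$time_h, s$level_cm)
    expect_equal(got$time_h, s$time_h[idx])
    expect_equal(got$level_cm, s$level_cm[idx])
  }
})

test_that("skipped fraction follows the inverted inundation count", {
  peaks <- seq(10, 100, by = 10)
  expect_equal(skipped_fraction(peaks, 5), 0)
  expect_equal(skipped_fraction(peaks, 150), 100)
  # 4 peaks above elevation 60: (1 - 4/10) * 100
  expect_equal(skipped_fraction(peaks, 60), 60)
  # a peak exactly at the elevation does not inundate
  expect_equal(skipped_fraction(peaks, 59.999), 50)
  expect_error(skipped_fraction(numeric(0), 10),
               class = "tidalmarsh_undefined_metric")
})

test_that("exposure curves are monotone steps at the peak levels", {
  t_h <- seq(0, 24.84, by = 1 / 6)
  one <- water_level_series(t_h, 300 * cos(2 * pi * t_h / 12.42) - 0)
  cv1 <- exposure_curve(one)
  expect_equal(eval_exposure(cv1, 299), 0)
  expect_equal(eval_exposure(cv1, 301), 100)

  s <- make_m2s2_series(days = 20, noise = 2, seed = 3)
  cv <- exposure_curve(s)
  expect_true(all(diff(cv$skipped_pct) >= 0))
  elevs <- seq(-250, 250, by = 7)
  peaks <- extract_high_tides(s)$level_cm
  expect_equal(eval_exposure(cv, elevs), skipped_fraction(peaks, elevs))
  expect_equal(eval_exposure(cv, elevs), oracle_skipped(peaks, elevs))
})

test_that("along-axis interpolation is piecewise linear and local", {
  mk <- function(pos, amp) {
    s <- make_m2s2_series(days = 15, m2 = 150 * amp, s2 = 50 * amp,
                          seed = 8, position = pos)
    exposure_curve(s)
  }
  curves <- list(mk(0, 1), mk(1000, 1.05), mk(2000, 1.1))
  elevs <- seq(0, 250, by = 10)

  at_station <- interpolate_exposure(curves, 1000)
  expect_equal(eval_exposure(at_station, elevs),
               eval_exposure(curves[[2]], elevs))

  mid <- interpolate_exposure(curves, 500)
  expect_equal(eval_exposure(mid, elevs),
               (eval_exposure(curves[[1]], elevs) +
                  eval_exposure(curves[[2]], elevs)) / 2)

  # a query between stations 2 and 3 ignores station 1
  q <- interpolate_exposure(curves, 1500)
  curves_alt <- list(mk(0, 3), curves[[2]], curves[[3]])
  q_alt <- interpolate_exposure(curves_alt, 1500)
  expect_equal(eval_exposure(q, elevs), eval_exposure(q_alt, elevs))

  # clamped outside the covered range
  expect_equal(eval_exposure(interpolate_exposure(curves, -500), elevs),
               eval_exposure(curves[[1]], elevs))
  expect_error(interpolate_exposure(list(), 0),
               class = "tidalmarsh_invalid_argument")
})

test_that("exposure rasters evaluate the local interpolated curve per cell", {
  s <- make_m2s2_series(days = 15, seed = 2)
  cv <- exposure_curve(s)
  low <- grid_raster(matrix(-300, 6, 6), kind = "elevation")
  expect_true(all(as.matrix(exposure_raster(low, cv)) == 0))

  set.seed(4)
  z <- matrix(runif(36, -100, 250), 6, 6)
  dem <- grid_raster(z, kind = "elevation")
  r <- as.matrix(exposure_raster(dem, cv))
  peaks <- extract_high_tides(s)$level_cm
  expect_equal(as.vector(r), skipped_fraction(peaks, as.vector(z)))

  z[2, 2] <- NA
  dem_na <- grid_raster(z, kind = "elevation")
  expect_true(is.na(as.matrix(exposure_raster(dem_na, cv))[2, 2]))
})

test_that("all exposure outputs are invariant to a common datum shift", {
  s <- make_m2s2_series(days = 15, noise = 2, seed = 10)
  shift <- 137
  s2 <- water_level_series(s$time_h, s$level_cm + shift)
  elevs <- seq(-100, 250, by = 13)
  cv <- exposure_curve(s)
  cv2 <- exposure_curve(s2)
  expect_equal(eval_exposure(cv, elevs), eval_exposure(cv2, elevs + shift))

  z <- matrix(seq(-50, 200, length.out = 25), 5, 5)
  r1 <- exposure_raster(grid_raster(z, kind = "elevation"), cv)
  r2 <- exposure_raster(grid_raster(z + shift, kind = "elevation"), cv2)
  expect_equal(as.matrix(r1), as.matrix(r2))
})

test_that("water-level CSV round trip preserves the series", {
  s1 <- make_m2s2_series(days = 3, seed = 1, position = 0)
  s2 <- make_m2s2_series(days = 3, seed = 2, position = 500)
  attr(s2, "station") <- "other"
  path <- withr::local_tempfile(fileext = ".csv")
  write_water_levels(list(s1, s2), path)
  back <- read_water_levels(path)
  expect_length(back, 2)
  pos <- sort(vapply(back, function(x) attr(x, "position_m"), numeric(1)))
  expect_equal(pos, c(0, 500))
  got <- back[[which(vapply(back, attr, "", which = "station") == "syn")]]
  expect_equal(got$level_cm, s1$level_cm)
  # timestamps rendered at second precision: times agree to 1 s
  expect_equal(got$time_h, s1$time_h, tolerance = 1 / 3600)
})
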