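test_that("hypsometric curves: degenerate, monotone and uniform cases", {
  all20 <- grid_raster(matrix(20, 5, 5), kind = "skipped")
  h <- hypsometric_curve(all20)
  expect_equal(h$rel_area_pct, 100)
  expect_equal(h$skipped_pct, 20)

  set.seed(3)
  r <- grid_raster(matrix(runif(400, 0, 100), 20, 20), kind = "skipped")
  hc <- hypsometric_curve(r)
  expect_true(all(diff(hc$rel_area_pct) <= 0))
  expect_equal(hc$rel_area_pct[1], 100)

  # uniform skipped% on (0, 100]: curve within 2% of the 100 - v line
  set.seed(4)
  big <- grid_raster(matrix(runif(1e5, 0, 100), 250, 400), kind = "skipped")
  hb <- hypsometric_curve(big)
  expect_lt(max(abs(hb$rel_area_pct - (100 - hb$skipped_pct))), 2)

  # invariant to cell permutation
  set.seed(5)
  v <- runif(100, 0, 100)
  h1 <- hypsometric_curve(grid_raster(matrix(v, 10, 10), kind = "skipped"))
  h2 <- hypsometric_curve(grid_raster(matrix(sample(v), 10, 10),
                                      kind = "skipped"))
  expect_equal(h1$rel_area_pct, h2$rel_area_pct)

  expect_error(hypsometric_curve(grid_raster(matrix(0, 3, 3),
                                             kind = "skipped")),
               class = "tidalmarsh_insufficient_data")
})

test_that("slope hypsometry groups by tidal position", {
  set.seed(8)
  sl <- grid_raster(matrix(runif(400, 0, 2), 20, 20), kind = "slope")
  ex <- grid_raster(matrix(runif(400, 1, 99), 20, 20), kind = "skipped")

  # single all-covering bin equals plain hypsometry of slope
  one <- slope_hypsometry(sl, ex, position_bins = 100)
  plain <- hyps_values_for_tests(as.vector(as.matrix(sl)))
  expect_equal(one$slope_deg, plain$value)
  expect_equal(one$rel_area_pct, plain$rel_area_pct)

  # constant slope: identical curves in all non-empty bins
  csl <- grid_raster(matrix(0.7, 20, 20), kind = "slope")
  multi <- slope_hypsometry(csl, ex, position_bins = c(25, 50, 75, 100))
  expect_true(all(multi$slope_deg == 0.7))
  expect_true(all(multi$rel_area_pct == 100))

  # synthetic convex flat: higher cells are flatter
  sc <- small_scene()
  yr <- as.character(sc$config$years[1])
  sh <- slope_hypsometry(sc$slope10[[yr]], sc$exposure10[[yr]],
                         position_bins = c(20, 100))
  med <- function(d) {
    d[which.min(abs(d$rel_area_pct - 50)), "slope_deg"][[1]]
  }
  lo_bin <- sh[sh$bin_low == 0, ]
  hi_bin <- sh[sh$bin_low == 20, ]
  expect_gt(med(lo_bin), med(hi_bin))
})

test_that("annual trends: exact lines, constants and CI coverage", {
  tf <- annual_trend(2001:2010, 2 * (2001:2010) + 5)
  expect_equal(tf$slope, 2, tolerance = 1e-12)
  expect_equal(tf$se, 0, tolerance = 1e-9)

  tc <- annual_trend(2001:2006, rep(7, 6))
  expect_equal(tc$slope, 0, tolerance = 1e-12)

  expect_error(annual_trend(c(2001, 2001), c(1, 2)),
               class = "tidalmarsh_invalid_argument")

  # 2 cm/yr + noise SD 0.5 over 10 years: 95% CI covers 2 in >= 90/100
  set.seed(77)
  covered <- 0
  for (i in 1:100) {
    vals <- 2 * (1:10) + rnorm(10, 0, 0.5)
    t <- annual_trend(1:10, vals)
    if (t$ci_low <= 2 && t$ci_high >= 2) covered <- covered + 1
  }
  expect_gte(covered, 90)
})

test_that("intensity-by-slope binning is logarithmic with missing empties", {
  set.seed(10)
  sl <- grid_raster(matrix(exp(runif(900, log(0.02), log(5))), 30, 30),
                    kind = "slope")
  cst <- grid_raster(matrix(0.5, 30, 30))
  tb <- intensity_by_slope(cst, sl)
  expect_equal(nrow(tb), 120)
  expect_true(all(tb$mean_intensity[tb$n > 0] == 0.5))
  expect_true(all(is.na(tb$mean_intensity[tb$n == 0])))
  # log-spaced edges
  expect_equal(diff(log(tb$bin_low[1:10])),
               rep(diff(log(c(tb$bin_low[1], tb$bin_high[1]))), 9))

  expect_error(
    intensity_by_slope(grid_raster(matrix(NA_real_, 3, 3)),
                       grid_raster(matrix(1, 3, 3), kind = "slope")),
    class = "tidalmarsh_insufficient_data")
})

test_that("establishment array: proportions, n-floor and pooling identity", {
  mk <- function(m, kind = "mask") grid_raster(m, cell_size = 10,
                                               kind = kind)
  n <- 10
  sk <- mk(matrix(40, n, n), kind = "skipped")
  it <- mk(matrix(0.5, n, n), kind = "other")
  early <- mk(matrix(FALSE, n, n))
  # 5 of 100 cells become vegetated: p = 0.05 in the single populated bin
  late_m <- matrix(FALSE, n, n); late_m[1, 1:5] <- TRUE
  pairs <- list(list(veg_early = early, veg_late = mk(late_m),
                     exposure = sk, intensity = it))
  ea <- establishment_array(pairs, intensity_breaks = seq(0, 1, length.out = 86))
  td <- tidy(ea)
  expect_equal(nrow(td), 1)
  expect_equal(td$p, 0.05)
  expect_equal(td$n, 100)
  expect_equal(td$skipped_low, 39.5)

  # a bin with 29 at-risk cells is absent from the output
  sk29 <- mk(matrix(c(rep(60, 29), rep(NA, 71)), n, n), kind = "skipped")
  ea29 <- establishment_array(list(list(veg_early = early, veg_late = mk(late_m),
                                        exposure = sk29, intensity = it)),
                              intensity_breaks = seq(0, 1, length.out = 86))
  expect_equal(nrow(tidy(ea29)), 0)
  expect_equal(sum(ea29$n), 29)

  # pooling: counts over two pair lists add, probabilities do not average
  late2 <- matrix(FALSE, n, n); late2[2, 1:9] <- TRUE
  p1 <- list(list(veg_early = early, veg_late = mk(late_m), exposure = sk,
                  intensity = it))
  p2 <- list(list(veg_early = early, veg_late = mk(late2), exposure = sk,
                  intensity = it))
  both <- establishment_array(c(p1, p2),
                              intensity_breaks = seq(0, 1, length.out = 86))
  expect_equal(tidy(both)$p, (5 + 9) / 200)
  expect_equal(tidy(both)$n, 200)
  avg <- establishment_array(c(p1, p2),
                             intensity_breaks = seq(0, 1, length.out = 86),
                             mode = "average")
  expect_equal(tidy(avg)$p, (0.05 + 0.09) / 2)

  # already vegetated cells leave the at-risk set
  early2 <- matrix(FALSE, n, n); early2[, 1:5] <- TRUE
  late3 <- matrix(TRUE, n, n)
  ea2 <- establishment_array(list(list(veg_early = mk(early2),
                                       veg_late = mk(late3),
                                       exposure = sk, intensity = it)),
                             intensity_breaks = seq(0, 1, length.out = 86))
  expect_equal(tidy(ea2)$n, 50)
  expect_equal(tidy(ea2)$p, 1)

  expect_error(establishment_array(list()),
               class = "tidalmarsh_invalid_argument")
})

test_that("the default establishment grid is 85 x 101", {
  mk <- function(m, kind = "mask") grid_raster(m, cell_size = 10,
                                               kind = kind)
  set.seed(2)
  sk <- mk(matrix(runif(100, 0, 100), 10, 10), kind = "skipped")
  it <- mk(matrix(runif(100, 0, 0.2), 10, 10), kind = "other")
  ea <- establishment_array(list(list(
    veg_early = mk(matrix(FALSE, 10, 10)),
    veg_late = mk(matrix(runif(100) < 0.2, 10, 10)),
    exposure = sk, intensity = it)))
  expect_equal(dim(ea$n), c(85L, 101L))
  expect_equal(ea$skipped_breaks, seq(-0.5, 100.5, 1))
})

test_that("indicator report flags accreting low-slope flats only", {
  mkd <- function(z) grid_raster(z, cell_size = 10, kind = "elevation")
  mke <- function(v) grid_raster(matrix(v, 12, 12), cell_size = 10,
                                 kind = "skipped")
  years <- 2001:2006
  gentle <- outer(rep(1, 12), seq(0, 22, length.out = 12)) # ~0.1 deg

  # accreting, gentle, above NHWL: flagged once the trend is estimable
  dems <- purrr::map(seq_along(years),
                     function(i) mkd(gentle + 2 * (i - 1)))
  names(dems) <- years
  exps <- purrr::map(seq_along(years), function(i) mke(5 + i))
  names(exps) <- years
  rep1 <- early_indicator_report(dems, exps)
  expect_true(any(rep1$flagged))
  expect_equal(attr(rep1, "first_flag_year"), 2003)

  # static steep flat: never flagged
  steep <- outer(rep(1, 12), seq(0, 220, length.out = 12)) # ~1 deg
  dems2 <- purrr::map(seq_along(years), function(i) mkd(steep))
  names(dems2) <- years
  rep2 <- early_indicator_report(dems2, exps)
  expect_false(any(rep2$flagged))

  # accreting flat below NHWL throughout: never flagged
  exps0 <- purrr::map(seq_along(years), function(i) mke(0))
  names(exps0) <- years
  rep3 <- early_indicator_report(dems, exps0)
  expect_false(any(rep3$flagged))

  expect_error(early_indicator_report(dems[1:2], exps[1:2]),
               class = "tidalmarsh_invalid_argument")
})
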