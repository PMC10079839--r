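test_that("Horn slope is exact on planes and zero on constants", {
  flat <- grid_raster(matrix(42, 8, 8), kind = "elevation")
  s <- slope_deg(flat)
  expect_true(all(as.matrix(s)[2:7, 2:7] == 0))
  expect_true(all(is.na(as.matrix(s)[1, ])))

  # 1 % grade: 1 cm rise per 1 m cell
  z <- outer(rep(1, 10), 0:9)
  s2 <- as.matrix(slope_deg(grid_raster(z, kind = "elevation")))
  expect_equal(max(abs(s2[2:9, 2:9] - atan(0.01) * 180 / pi)), 0,
               tolerance = 1e-9)

  expect_error(slope_deg(grid_raster(z, kind = "reflectance")),
               class = "tidalmarsh_semantic_type")
  expect_error(slope_deg(grid_raster(matrix(0, 2, 2), kind = "elevation")),
               class = "tidalmarsh_invalid_argument")
})

test_that("Horn slope matches a central-difference oracle on smooth fields", {
  set.seed(5)
  rough <- matrix(rnorm(64 * 64, 0, 20), 64, 64)
  smooth <- box_blur_for_tests(rough, 9)
  g <- grid_raster(smooth, cell_size = 2, kind = "elevation")
  horn <- as.matrix(slope_deg(g))
  oracle <- oracle_slope_deg(smooth, 2)
  inner <- 2:63
  rms <- sqrt(mean((horn[inner, inner] - oracle[inner, inner])^2))
  expect_lt(rms, 0.05)
})

test_that("Horn slope is invariant to datum shifts and equivariant to rotation", {
  set.seed(6)
  z <- matrix(rnorm(100, 100, 5), 10, 10)
  a <- as.matrix(slope_deg(grid_raster(z, kind = "elevation")))
  b <- as.matrix(slope_deg(grid_raster(z + 250, kind = "elevation")))
  expect_equal(a, b, tolerance = 1e-12)
  rot <- t(z)[ncol(z):1, ]
  sr <- as.matrix(slope_deg(grid_raster(rot, kind = "elevation")))
  sa_rot <- t(a)[ncol(a):1, ]
  expect_equal(sr, sa_rot, tolerance = 1e-12)
})

test_that("block_resample aggregates blocks and honours nodata rules", {
  g <- grid_raster(matrix(c(1, 3, 2, 4), 2, 2), cell_size = 1)
  expect_equal(as.vector(as.matrix(block_resample(g, 2, "mean"))), 2.5)
  expect_equal(as.vector(as.matrix(block_resample(g, 2, "sd"))),
               sd(c(1, 2, 3, 4)))

  cst <- grid_raster(matrix(7, 4, 4))
  expect_equal(as.vector(as.matrix(block_resample(cst, 2, "sd"))),
               rep(0, 4))

  bool <- grid_raster(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2),
                      kind = "mask")
  expect_true(as.vector(as.matrix(block_resample(bool, 2, "max"))))

  holey <- matrix(c(1, NA, NA, NA), 2, 2)
  hg <- grid_raster(holey)
  expect_equal(as.vector(as.matrix(block_resample(hg, 2, "mean"))), 1)
  expect_true(is.na(as.vector(as.matrix(block_resample(hg, 2, "sd")))))
  expect_true(is.na(as.vector(as.matrix(block_resample(hg, 2, "max")))))

  expect_error(block_resample(g, 2.5, "mean"),
               class = "tidalmarsh_invalid_argument")
})

test_that("block mean conserves the global mean on fully valid grids", {
  set.seed(9)
  g <- grid_raster(matrix(runif(400), 20, 20), cell_size = 1)
  rm10 <- block_resample(g, 10, "mean")
  expect_equal(mean(as.matrix(rm10)), mean(as.matrix(g)), tolerance = 1e-9)
})

test_that("focal_sd matches closed forms and ignores constants", {
  cst <- grid_raster(matrix(5, 20, 20), cell_size = 1)
  expect_true(all(as.matrix(focal_sd(cst, 10)) == 0))

  # balanced 0/100 checkerboard: SD = 100 * sqrt(0.25 * 100 / 99)
  chk <- outer(1:10, 1:10, function(i, j) 100 * ((i + j) %% 2))
  v <- as.vector(as.matrix(focal_sd(grid_raster(chk), 10)))
  expect_equal(v, 100 * sqrt(0.25 * 100 / 99), tolerance = 1e-12)

  sparse <- matrix(NA_real_, 4, 4)
  sparse[1, 1] <- 3
  expect_true(is.na(as.vector(as.matrix(focal_sd(grid_raster(sparse), 4)))))

  expect_error(focal_sd(grid_raster(matrix(0, 4, 4), cell_size = 10), 5),
               class = "tidalmarsh_invalid_argument")
})

test_that("focal_sd is shift-invariant and window-translation equivariant", {
  set.seed(11)
  m <- matrix(rnorm(900), 30, 30)
  a <- as.matrix(focal_sd(grid_raster(m), 10))
  b <- as.matrix(focal_sd(grid_raster(m + 123.4), 10))
  expect_equal(a, b, tolerance = 1e-9)

  shifted <- m[, c(11:30, 1:10)] # shift by one full window
  s <- as.matrix(focal_sd(grid_raster(shifted), 10))
  expect_equal(s, a[, c(2, 3, 1)], tolerance = 1e-12)
})

test_that("apply_masks is a union operation with nodata semantics", {
  g <- grid_raster(matrix(1:16, 4, 4))
  expect_identical(as.matrix(apply_masks(g, list())), as.matrix(g))

  all_true <- grid_raster(matrix(TRUE, 4, 4), kind = "mask")
  expect_true(all(is.na(as.matrix(apply_masks(g, list(all_true))))))

  m1 <- grid_raster(matrix(c(TRUE, rep(FALSE, 15)), 4, 4), kind = "mask")
  m2 <- grid_raster(matrix(c(rep(FALSE, 15), TRUE), 4, 4), kind = "mask")
  both <- apply_masks(g, list(m1, m2))
  union <- grid_raster(as.matrix(m1) | as.matrix(m2), kind = "mask")
  expect_identical(as.matrix(both), as.matrix(apply_masks(g, list(union))))
  expect_identical(as.matrix(apply_masks(both, list(m1, m2))),
                   as.matrix(both))

  small <- grid_raster(matrix(TRUE, 2, 2), kind = "mask")
  expect_error(apply_masks(g, list(small)),
               class = "tidalmarsh_coregistration")
})
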