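test_that("z-projection unions slices and keeps the pixel grid", {
  m <- array(FALSE, c(1, 6, 7)); m[1, 2:3, 2:4] <- TRUE
  pr <- project_mask(vox_mask(m, c(2, 0.5, 0.25)))
  expect_identical(pr$image, matrix(m[1, , ], 6, 7))
  expect_equal(pr$pixel_size, c(0.5, 0.25))

  m2 <- array(FALSE, c(2, 6, 6))
  m2[1, 1:2, 1:2] <- TRUE
  m2[2, 5:6, 5:6] <- TRUE
  pr2 <- project_mask(vox_mask(m2, c(1, 1, 1)))
  expect_equal(sum(pr2$image), 8)

  # ellipsoid projects to its equatorial ellipse (within a pixel)
  spec <- ideal_spec(phantom_preset("panc1_like", seed = 9))
  spec$cells[[1]]$nucleus$perturb_amp <- 0
  ph <- generate_cell_phantom(spec)
  pr3 <- project_mask(ph$labels$nucleus)
  a <- spec$cells[[1]]$nucleus$semi_axes
  expect_equal(sum(pr3$image) * prod(pr3$pixel_size), pi * a[1] * a[2],
               tolerance = 0.02)
  expect_error(project_mask(vox_mask(array(FALSE, c(2, 2, 2)), c(1, 1, 1))),
               "empty")
})

test_that("Feret diameters recover calibrated discs and ellipses", {
  # disc radius 5 um at 0.1 um pixels
  ax <- (0:119) * 0.1 - 6
  d2 <- outer(ax^2, ax^2, "+")
  disc <- d2 <= 25
  fd <- feret_diameters(disc, c(0.1, 0.1))
  expect_equal(fd[["D1"]], 10, tolerance = 0.1 / 5)
  expect_equal(fd[["D2"]], 10, tolerance = 0.1 / 5)

  # epithelial cell-body ellipse (44.6 x 35.9 um), rotated
  th <- 25 * pi / 180
  axu <- (0:239) * 0.25 - 30
  X <- matrix(axu, 240, 240, byrow = TRUE)
  Y <- matrix(axu, 240, 240)
  xr <- cos(th) * X + sin(th) * Y
  yr <- -sin(th) * X + cos(th) * Y
  ell <- (xr / 22.3)^2 + (yr / 17.95)^2 <= 1
  fd2 <- feret_diameters(ell, c(0.25, 0.25))
  expect_equal(fd2[["D1"]], 44.6, tolerance = 0.02)
  expect_equal(fd2[["D2"]], 35.9, tolerance = 0.02)
})

test_that("calipers agree with the dense direction-scan oracle", {
  set.seed(11)
  for (k in 1:20) {
    img <- matrix(FALSE, 40, 40)
    pts <- cbind(sample(5:36, 20, replace = TRUE),
                 sample(5:36, 20, replace = TRUE))
    img[pts] <- TRUE
    px <- c(runif(1, 0.2, 1), runif(1, 0.2, 1))
    fd <- feret_diameters(img, px)
    or <- feret_oracle(img, px)
    expect_equal(fd[["D1"]], or[["D1"]], tolerance = 1e-4)
    # min caliper vs 0.5 degree scan: within the angular discretization
    expect_lte(fd[["D2"]], or[["D2"]] + 1e-9)
    expect_equal(fd[["D2"]], or[["D2"]], tolerance = 0.01)
  }
})

test_that("object records carry diameters, area and volume per component", {
  m <- array(FALSE, c(12, 30, 30))
  ax <- seq_len(30) - 1
  d2a <- outer((ax - 7)^2, (ax - 7)^2, "+")
  d2b <- outer((ax - 22)^2, (ax - 22)^2, "+")
  for (z in 4:9) {
    m[z, , ] <- m[z, , ] | (d2a + (z - 6.5)^2 <= 16) |
      (d2b + (z - 6.5)^2 <= 16)
  }
  rec <- measure_objects(vox_mask(m, c(1, 1, 1)), min_voxels = 10)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$D1_um[1], rec$D1_um[2])
  expect_equal(rec$volume_um3[1], rec$volume_um3[2])
  expect_equal(rec$Davg_um, (rec$D1_um + rec$D2_um) / 2)
  expect_true(all(rec$D1_um >= rec$D2_um))

  # small components are filtered
  m[1, 1, 1] <- TRUE
  rec2 <- measure_objects(vox_mask(m, c(1, 1, 1)), min_voxels = 10)
  expect_equal(nrow(rec2), 2L)
  rec3 <- measure_objects(vox_mask(m, c(1, 1, 1)), min_voxels = 1)
  expect_equal(nrow(rec3), 3L)

  # empty mask: empty frame
  expect_equal(nrow(measure_objects(vox_mask(array(FALSE, c(2, 2, 2)),
                                             c(1, 1, 1)))), 0L)

  # diameters scale linearly with pixel size
  rec_small <- measure_objects(vox_mask(m, c(1, 0.5, 0.5)), min_voxels = 10)
  expect_equal(rec_small$D1_um, rec$D1_um / 2)
})

test_that("highly elongated objects are flagged for Davg suppression", {
  m <- array(FALSE, c(3, 8, 60))
  m[2, 3:6, 3:58] <- TRUE
  rec <- measure_objects(vox_mask(m, c(1, 1, 1)), min_voxels = 10)
  expect_true(rec$davg_suppressed)
  expect_false(is.na(rec$Davg_um))  # still computed
})
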