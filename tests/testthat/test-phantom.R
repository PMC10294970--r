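test_that("fixed seeds reproduce phantoms bit-for-bit", {
  spec <- phantom_preset("panc1_like", seed = 21)
  spec$shape <- c(8L, 96L, 96L)
  spec$cells[[1]]$center <- c(12, 12, 3.5)
  spec$cells[[1]]$semi_axes <- c(9, 7, 2.6)
  spec$cells[[1]]$nucleus <- list(semi_axes = c(4, 3, 1.8))
  a <- generate_cell_phantom(spec)
  b <- generate_cell_phantom(spec)
  expect_identical(a$stack$data, b$stack$data)
  spec2 <- spec; spec2$seed <- 22L
  c2 <- generate_cell_phantom(spec2)
  expect_false(identical(a$stack$data, c2$stack$data))
  # generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_cell_phantom(spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("ground-truth labels nest: nucleus inside cell, shell on its rim", {
  for (preset in c("panc1_like", "shsy5y_like")) {
    ph <- generate_cell_phantom(ideal_spec(phantom_preset(preset, seed = 2)))
    expect_true(all(ph$labels$cell$data[ph$labels$nucleus$data]))
    expect_true(all(ph$labels$cell$data[ph$labels$shell$data]))
    expect_false(any(ph$labels$shell$data &
                       !ph$labels$cell$data))
  }
  bad <- phantom_preset("panc1_like", seed = 2)
  bad$cells[[1]]$nucleus$offset <- c(30, 0, 0)
  expect_error(generate_cell_phantom(bad), "not contained")
})

test_that("degenerate blur and noise leave exact label intensities", {
  spec <- ideal_spec(phantom_preset("panc1_like", seed = 5))
  spec$shape <- c(8L, 80L, 80L)
  spec$cells[[1]]$center <- c(10, 10, 3.5)
  spec$cells[[1]]$semi_axes <- c(8, 6, 2.5)
  spec$cells[[1]]$nucleus <- list(semi_axes = c(3.5, 2.8, 1.6))
  ph <- generate_cell_phantom(spec)
  tritc <- get_channel(ph$stack, "TRITC")
  ints <- spec$intensities
  expect_true(all(tritc[ph$labels$shell$data] == ints$shell))
  expect_true(all(tritc[!ph$labels$shell$data] == ints$background))
  dapi <- get_channel(ph$stack, "DAPI")
  expect_true(all(dapi[ph$labels$nucleus$data] == ints$nucleus))
})

test_that("presets encode the three imaging geometries", {
  p1 <- phantom_preset("panc1_like")
  expect_equal(p1$shape[1], 16L)
  expect_equal(p1$shape[1] * p1$voxel_size[1], 15)
  expect_equal(p1$cells[[1]]$semi_axes[1:2] * 2, c(44.6, 35.9))
  expect_equal(p1$cells[[1]]$nucleus$semi_axes[1:2] * 2, c(18.8, 13.7))

  p2 <- phantom_preset("hdf_like")
  expect_equal(p2$shape[1], 33L)
  expect_equal(p2$shape[1] * p2$voxel_size[1], 16)
  expect_length(p2$cells, 2L)
  expect_gt(length(p2$fibers), 0L)
  expect_equal(p2$cells[[1]]$semi_axes[1] * 2, 195.5)
  ph2 <- generate_cell_phantom(ideal_spec(p2))
  expect_equal(length(ph2$stack$channels), 3L)  # TRITC, DAPI, AF647

  p3 <- phantom_preset("shsy5y_like")
  expect_equal(p3$shape[1], 36L)
  expect_equal(p3$shape[1] * p3$voxel_size[1], 10)
  reach <- max(vapply(p3$cells[[1]]$protrusions, `[[`, 0, "length_um"))
  expect_equal(2 * reach, 16.5)  # opposed protrusion tips span D1

  expect_error(phantom_preset("hela_like"), "arg")
})

test_that("half-maximum segmentation of a blurred phantom recovers the
           nucleus (Dice >= 0.95)", {
  spec <- phantom_preset("panc1_like", seed = 3)
  spec$noise <- list(type = "none")  # PSF on, detector noise off
  ph <- generate_cell_phantom(spec)
  img <- get_channel(ph$stack, "DAPI")
  thr <- (max(img) + min(img)) / 2
  m <- threshold_mask(ph$stack, "DAPI", c(thr, 255))
  gt <- ph$labels$nucleus$data
  dice <- 2 * sum(m$data & gt) / (sum(m$data) + sum(gt))
  expect_gte(dice, 0.95)
})
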