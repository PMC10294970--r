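make_stack <- function(arr3d, voxel_size = c(1, 1, 1), name = "ch") {
  voxel_stack(array(arr3d, dim = c(1, dim(arr3d))), voxel_size, name)
}

test_that("grey-value thresholding keeps exactly the in-band voxels", {
  stk <- make_stack(array(100, dim = c(4, 5, 6)))
  expect_true(all(threshold_mask(stk, "ch", c(50, 200))$data))
  expect_true(all(threshold_mask(stk, "ch", c(0, 255))$data))
  expect_error(threshold_mask(stk, "ch", c(0, 300)), "maximum")
  expect_error(threshold_mask(stk, "nope", c(0, 255)), "unknown channel")

  # exact recovery of a noise-free phantom shell against ground truth
  spec <- ideal_spec(phantom_preset("panc1_like", seed = 2))
  spec$shape <- c(10L, 64L, 64L)
  spec$voxel_size <- c(1, 0.5, 0.5)
  spec$cells[[1]]$center <- c(16, 16, 4.5)
  spec$cells[[1]]$semi_axes <- c(11, 9, 3.5)
  spec$cells[[1]]$nucleus <- list(semi_axes = c(4, 3.2, 2))
  ph <- generate_cell_phantom(spec)
  m <- threshold_mask(ph$stack, "TRITC", c(100, 255))
  expect_equal(sum(m$data), sum(ph$labels$shell$data))
  expect_identical(m$data, ph$labels$shell$data)
})

test_that("dynamic region grow matches an iterative flood-fill oracle", {
  img <- array(0, dim = c(5, 12, 12))
  img[2:4, 2:5, 2:5] <- 150   # blob A
  img[2:4, 8:11, 8:11] <- 150 # blob B, disjoint
  stk <- make_stack(img)
  m <- region_grow(stk, "ch", seed = c(3, 3, 3), low = 100, high = 200)
  oracle <- flood_oracle(img, c(3, 3, 3), 100, 200)
  expect_identical(m$data, oracle)
  expect_equal(sum(m$data), 3 * 4 * 4)  # only blob A

  # uniform grid: grows to everything
  u <- make_stack(array(7, dim = c(3, 4, 5)))
  expect_true(all(region_grow(u, "ch", c(1, 1, 1), 0, 10)$data))

  # singleton: only the seed carries the value
  img2 <- array(0, dim = c(3, 3, 3)); img2[2, 2, 2] <- 99
  s2 <- make_stack(img2)
  expect_equal(sum(region_grow(s2, "ch", c(2, 2, 2), 99, 99)$data), 1)
  expect_error(region_grow(stk, "ch", seed = c(1, 1, 1), 100, 200),
               "seed intensity")
})

test_that("region grow is contained in the threshold band and connected", {
  img <- random_mask(c(8, 12, 12), p = 0.4, seed = 5) * 100
  stk <- make_stack(array(img, dim = dim(img)))
  seeds <- which(img == 100, arr.ind = TRUE)
  for (k in c(1, 5, 9)) {
    sd <- seeds[k, ]
    m <- region_grow(stk, "ch", sd, 50, 150)
    thr <- threshold_mask(stk, "ch", c(50, 150))
    expect_true(all(thr$data[m$data]))        # subset of the band
    expect_length(split_mask(m), 1L)          # single 26-connected blob
  }
})

test_that("split_mask orders disjoint components whose union is the input", {
  m <- array(FALSE, dim = c(10, 10, 10))
  m[2:4, 2:4, 2:4] <- TRUE  # 27 voxels
  m[7:8, 7:8, 7:8] <- TRUE  # 8 voxels
  parts <- split_mask(vox_mask(m, c(1, 1, 1)))
  expect_length(parts, 2L)
  expect_equal(vapply(parts, mask_count, 0), c(27, 8))
  expect_equal(parts[[1]]$data | parts[[2]]$data, m)
  expect_false(any(parts[[1]]$data & parts[[2]]$data))

  ball <- ball_mask(4, 1)
  expect_identical(split_mask(ball)[[1]]$data, ball$data)
  expect_length(split_mask(vox_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1))),
                0L)

  # property over random masks: exact partition
  for (seed in 1:4) {
    rm <- vox_mask(random_mask(seed = seed), c(1, 1, 1))
    parts <- split_mask(rm)
    un <- Reduce(`|`, lapply(parts, `[[`, "data"))
    expect_identical(un, rm$data)
    expect_equal(sum(vapply(parts, mask_count, 0)), mask_count(rm))
    expect_false(is.unsorted(rev(vapply(parts, mask_count, 0))))
  }
})

test_that("crop keeps registration and zeroes outside the ROI", {
  m <- array(FALSE, dim = c(6, 12, 12))
  m[2:4, 2:5, 2:5] <- TRUE
  m[2:4, 8:11, 8:11] <- TRUE
  mk <- vox_mask(m, c(1, 1, 1))
  full <- crop_mask(mk, roi(c(1, 7), c(1, 13), c(1, 13)))
  expect_identical(full$data, m)
  onlyA <- crop_mask(mk, roi(c(1, 7), c(1, 7), c(1, 7)))
  expect_equal(sum(onlyA$data), 3 * 4 * 4)
  expect_identical(dim(onlyA$data), dim(m))
  none <- crop_mask(mk, roi(c(5, 6), c(6, 8), c(6, 8)))
  expect_equal(sum(none$data), 0)
  expect_error(crop_mask(mk, roi(c(1, 20), c(1, 2), c(1, 2))),
               "out of bounds")
})

test_that("fill closes a hollow shell into the flood-fill-oracle solid", {
  # hollow ball shell, closed: interior must fill
  ball <- ball_mask(6, 1)
  shell <- ball$data
  # carve the interior with the analytic inner ball (same centre offsets)
  d <- dim(ball$data)
  ax <- lapply(1:3, function(i) seq_len(d[i]) - 1)
  ctr <- (d - 1) / 2 + 0.2
  d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
              (ax[[3]] - ctr[3])^2, "+")
  shell[d2 <= 4.4^2] <- FALSE
  sm <- vox_mask(shell, c(1, 1, 1))
  filled <- fill_mask(sm, "volumetric", radius = 0)
  # oracle: background not 6-reachable from the border is a hole
  bg <- flood_oracle((!shell) * 1, c(1, 1, 1), 1, 1, conn = 6)
  expect_identical(filled$data, shell | (!shell & !bg))
  expect_equal(sum(filled$data), sum(d2 <= 6^2))

  # already solid: identity (hole fill alone, and closing of a solid box)
  expect_identical(fill_mask(ball, "volumetric", 0)$data, ball$data)
  box <- array(FALSE, c(12, 12, 12)); box[3:10, 3:10, 3:10] <- TRUE
  bm <- vox_mask(box, c(1, 1, 1))
  expect_identical(fill_mask(bm, "volumetric", 2)$data, box)

  # extensive and idempotent on random masks
  for (seed in 1:3) {
    rm <- vox_mask(random_mask(c(9, 9, 9), 0.25, seed), c(1, 1, 1))
    f1 <- fill_mask(rm, "volumetric", 2)
    expect_true(all(f1$data[rm$data]))
    expect_identical(fill_mask(f1, "volumetric", 2)$data, f1$data)
  }
})

test_that("per-slice fill operates on z-planes independently", {
  m <- array(FALSE, dim = c(3, 15, 15))
  # annulus in slice 2
  ax <- seq_len(15) - 8
  d2 <- outer(ax^2, ax^2, "+")
  m[2, , ] <- d2 <= 36 & d2 >= 16
  mk <- vox_mask(m, c(1, 1, 1))
  f <- fill_mask(mk, "per_slice")
  expect_equal(matrix(f$data[2, , ], 15), d2 <= 36)
  expect_equal(sum(f$data[1, , ]), 0)
  expect_equal(sum(f$data[3, , ]), 0)
})

test_that("mask edits apply set regions before clear regions", {
  empty <- vox_mask(array(FALSE, c(5, 5, 5)), c(1, 1, 1))
  r <- roi(c(2, 4), c(2, 4), c(2, 4))
  s <- edit_mask(empty, set_regions = list(r))
  expect_equal(sum(s$data), 8)
  expect_equal(sum(edit_mask(empty, set_regions = list(r),
                             clear_regions = list(r))$data), 0)
  cube <- edit_mask(empty, set_regions = list(roi(c(1, 5), c(1, 5), c(1, 5))))
  corner <- roi(c(1, 3), c(1, 3), c(1, 3))
  expect_equal(sum(edit_mask(cube, clear_regions = list(corner))$data),
               4^3 - 2^3)
})
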