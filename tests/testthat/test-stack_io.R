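test_that("multi-channel TIFF stacks round-trip bit-identically", {
  spec <- ideal_spec(phantom_preset("panc1_like", seed = 3))
  spec$shape <- c(8L, 48L, 48L)
  spec$cells[[1]]$center <- c(6, 6, 3.5)
  spec$cells[[1]]$semi_axes <- c(4.5, 3.5, 2.5)
  spec$cells[[1]]$nucleus <- list(semi_axes = c(2, 1.6, 1.4))
  ph <- generate_cell_phantom(spec)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(ph$stack, path)
  rd <- read_stack(path, voxel_size = ph$stack$voxel_size,
                   channels = c("TRITC", "DAPI"))
  expect_identical(dim(rd$data), dim(ph$stack$data))
  expect_equal(rd$data, ph$stack$data)
  # canonical axis order: re-reading gives identical grids
  rd2 <- read_stack(path, voxel_size = ph$stack$voxel_size,
                    channels = c("TRITC", "DAPI"))
  expect_identical(rd$data, rd2$data)
})

test_that("page layout, channel count and voxel-size rules are enforced", {
  pages <- lapply(1:6, function(i) matrix(i / 10, 4, 5))
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  # z-fastest vs c-fastest arrange pages differently
  a <- read_stack(path, voxel_size = c(1, 1, 1), channels = c("a", "b"),
                  layout = "c_fastest")
  b <- read_stack(path, voxel_size = c(1, 1, 1), channels = c("a", "b"),
                  layout = "z_fastest")
  # page 2 is channel 2 / z 1 when channel-interleaved, channel 1 / z 2
  # when z-fastest
  expect_equal(a$data[2, 1, 1, 1], b$data[1, 2, 1, 1])
  expect_equal(a$data[2, 1, 1, 1], round(2 / 10 * 255))
  expect_equal(dim(a$data), c(2L, 3L, 4L, 5L))
  expect_error(read_stack(path, voxel_size = c(1, 1, 1),
                          channels = c("a", "b", "c", "d")),
               "not divisible")
  expect_error(read_stack(path), "voxel size")
  # single-page all-zero stack
  p0 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0, 4, 4)), p0, bits.per.sample = 8L,
                  compression = "none")
  z <- read_stack(p0, voxel_size = c(1, 1, 1), channels = "only")
  expect_true(all(z$data == 0))
})

test_that("physical extent validation reports per-axis pass and fail", {
  arr <- array(0, dim = c(1, 16, 8, 8))
  stk <- voxel_stack(arr, c(0.9375, 0.25, 0.25), "ch1")
  r <- validate_scale(stk, c(z = 15), tol = 0.01)
  expect_true(r$pass)
  expect_equal(r$computed_um, 15)
  # exact equality passes at zero tolerance
  expect_true(validate_scale(stk, c(z = 15), tol = 0)$pass)
  stk2 <- voxel_stack(array(0, dim = c(1, 36, 4, 4)), c(0.25, 1, 1), "ch1")
  r2 <- validate_scale(stk2, c(z = 10), tol = 0.01)
  expect_false(r2$pass)
  expect_equal(r2$computed_um, 9)
})

test_that("STL write/read round-trips face counts and float32 vertices", {
  tet <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(tet, path)
  expect_equal(readBin(path, integer(), n = 1, size = 4, endian = "little",
                       signed = TRUE) * 0 + file.info(path)$size,
               84 + 50 * 4)
  rd <- read_stl(path)
  expect_equal(nrow(rd$faces), 4L)
  expect_equal(sort(rd$vertices[, 1]), sort(tet$vertices[, 1]),
               tolerance = 1e-7)

  sph <- solidify(sphere_mesh(5, 3), 1, "filled")
  p2 <- withr::local_tempfile(fileext = ".stl")
  write_stl(sph, p2)
  rd2 <- read_stl(p2)
  expect_equal(nrow(rd2$faces), nrow(sph$faces))
  expect_equal(max(abs(rd2$vertices)), max(abs(sph$vertices)),
               tolerance = 1e-6)
  expect_true(mesh_stats(rd2)$watertight)

  p3 <- withr::local_tempfile(fileext = ".stl")
  write_stl(tet, p3, mode = "ascii")
  expect_match(readLines(p3, n = 1), "^solid")
  rd3 <- read_stl(p3)
  expect_equal(nrow(rd3$faces), 4L)

  empty <- surface_mesh(matrix(numeric(), 0, 3), matrix(integer(), 0, 3))
  expect_error(write_stl(empty, path), "empty")
})
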