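test_that("iso-surface volume matches analytic digitized primitives", {
  ball <- ball_mask(10, 0.5)
  s <- extract_surface(ball)
  st <- mesh_stats(s)
  expect_true(st$watertight)
  expect_equal(st$n_components, 1L)
  expect_equal(st$volume, 4 / 3 * pi * 1000, tolerance = 0.02)
  # independent slow oracle on a small ball
  small <- extract_surface(ball_mask(3, 0.6))
  expect_equal(mesh_stats(small)$volume, volume_oracle(small),
               tolerance = 1e-10)

  # single 1 um^3 voxel: closed wrap of about unit volume
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  st1 <- mesh_stats(extract_surface(vox_mask(m1, c(1, 1, 1))))
  expect_true(st1$watertight)
  expect_gt(st1$volume, 0.7)
  expect_lte(st1$volume, 1.0)

  # anisotropic spacing honoured: same ball, dz = 2 dx
  aniso <- ball_mask(10, voxel_size = c(1, 0.5, 0.5))
  expect_equal(mesh_stats(extract_surface(aniso))$volume, 4 / 3 * pi * 1000,
               tolerance = 0.02)

  expect_error(extract_surface(vox_mask(array(FALSE, c(2, 2, 2)),
                                        c(1, 1, 1))), "empty")
})

test_that("iso-surface volume error shrinks as voxels shrink", {
  err <- vapply(c(1, 0.5), function(h) {
    v <- mesh_stats(extract_surface(ball_mask(8, h)))$volume
    abs(v - 4 / 3 * pi * 512) / (4 / 3 * pi * 512)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("Taubin smoothing relaxes area, preserves volume and topology", {
  s <- extract_surface(ball_mask(8, 0.5))
  expect_identical(smooth_mesh(s, 0), s)
  v0 <- mesh_stats(s)$volume
  areas <- numeric(3); sm <- s
  for (k in 1:3) {
    sm <- smooth_mesh(sm, 5)
    areas[k] <- mesh_stats(sm)$area
  }
  expect_false(is.unsorted(rev(areas)))          # monotone decrease
  expect_lt(mesh_stats(sm)$area, mesh_stats(s)$area)
  expect_equal(mesh_stats(sm)$volume, v0, tolerance = 0.05)
  expect_true(mesh_stats(sm)$watertight)
  expect_identical(dim(sm$faces), dim(s$faces))  # topology untouched

  # digitized cube: no vertex strays farther than one voxel
  mc <- array(FALSE, c(12, 12, 12)); mc[3:10, 3:10, 3:10] <- TRUE
  cm <- extract_surface(vox_mask(mc, c(1, 1, 1)))
  cs <- smooth_mesh(cm, 10)
  expect_lt(max(abs(cs$vertices - cm$vertices)), 1)
})

test_that("decimation respects the face budget and watertightness", {
  s <- smooth_mesh(extract_surface(ball_mask(10, 0.5)), 5)
  expect_identical(decimate_mesh(s, 1), s)
  d <- decimate_mesh(s, 0.25)
  expect_lte(nrow(d$faces), ceiling(0.25 * nrow(s$faces)))
  expect_true(mesh_stats(d)$watertight)
  expect_equal(mesh_stats(d)$volume, mesh_stats(s)$volume, tolerance = 0.05)
  # a simplex cannot be reduced further: reported as-is
  tet <- tetra_mesh()
  expect_identical(decimate_mesh(tet, 0.5), tet)
})

test_that("mesh statistics report area, volume and watertightness", {
  cu <- cube_mesh(1)
  st <- mesh_stats(cu)
  expect_equal(st$area, 6)
  expect_equal(st$volume, 1)
  expect_true(st$watertight)
  expect_equal(st$n_components, 1L)

  sp <- sphere_mesh(10, 4)
  expect_equal(mesh_stats(sp)$area, 4 * pi * 100, tolerance = 0.02)
  expect_equal(mesh_stats(sp)$volume, 4 / 3 * pi * 1000, tolerance = 0.02)

  holed <- surface_mesh(cu$vertices, cu$faces[-1, ], unit = "mm")
  sth <- mesh_stats(holed)
  expect_false(sth$watertight)
  expect_true(is.na(sth$volume))

  two <- surface_mesh(rbind(cu$vertices, cu$vertices + 5),
                      rbind(cu$faces, cu$faces + 8L), unit = "mm")
  expect_equal(mesh_stats(two)$n_components, 2L)
})

test_that("distance measurement is Euclidean and scale-linear", {
  expect_equal(measure_distance(NULL, c(0, 0, 0), c(3, 4, 0)), 5)
  sp <- sphere_mesh(10, 2, unit = "um")
  map <- make_scale_map(10, 10)  # M = 1000
  spm <- apply_scale(sp, map)
  a <- sp$vertices[1, ]; b <- sp$vertices[10, ]
  expect_equal(measure_distance(spm, 1, 10),
               measure_distance(sp, a, b))  # rescale of r=10 "um" sphere
  expect_equal(measure_distance(NULL, c(0, 0, 0) * 1000, c(3, 4, 0) * 1000),
               5000)

  # phantom nucleus principal axis recovered within one voxel
  spec <- ideal_spec(phantom_preset("panc1_like", seed = 4))
  spec$cells[[1]]$nucleus$perturb_amp <- 0
  ph <- generate_cell_phantom(spec)
  mesh <- extract_surface(ph$labels$nucleus)
  th <- spec$cells[[1]]$theta_deg * pi / 180
  u <- c(cos(th), sin(th), 0)
  pr <- mesh$vertices %*% u
  expect_equal(max(pr) - min(pr), 2 * spec$cells[[1]]$nucleus$semi_axes[1],
               tolerance = 1 / (2 * 9.4))  # within ~1 voxel of 18.8 um
})

test_that("measurements commute with uniform rescaling", {
  s <- smooth_mesh(extract_surface(ball_mask(5, 0.5)), 3)
  map <- make_scale_map(1, 2)  # M = 2000, factor 2
  sm <- apply_scale(s, map)
  expect_equal(mesh_stats(sm)$area, 4 * mesh_stats(s)$area)
  expect_equal(mesh_stats(sm)$volume, 8 * mesh_stats(s)$volume)
  expect_equal(measure_distance(sm, 1, 5), 2 * measure_distance(s, 1, 5))
})
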