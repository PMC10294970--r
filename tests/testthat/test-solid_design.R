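test_that("uniform offset solidification matches analytic shell volumes", {
  sp <- sphere_mesh(10, 4)
  sh <- solidify(sp, 1, "shell")
  expect_true(mesh_stats(sh)$watertight)
  expect_equal(mesh_stats(sh)$volume, 4 / 3 * pi * (11^3 - 10^3),
               tolerance = 0.05)
  fi <- solidify(sp, 1, "filled")
  expect_true(mesh_stats(fi)$watertight)
  expect_equal(mesh_stats(fi)$volume, 4 / 3 * pi * 11^3, tolerance = 0.05)
  expect_error(solidify(sp, 0), "thickness")
})

test_that("open surfaces solidify into watertight parts", {
  s <- sphere_mesh(10, 3)
  keep <- apply(s$faces, 1, function(fc) all(s$vertices[fc, 3] >= -1e-9))
  hemi <- surface_mesh(s$vertices, s$faces[keep, ], unit = "mm")
  expect_false(mesh_stats(hemi)$watertight)
  part <- solidify(hemi, 1, "filled")
  st <- mesh_stats(part)
  expect_true(st$watertight)
  expect_gt(st$volume, 0)
})

test_that("plane splitting conserves volume with flat caps", {
  cu <- solid_part(cube_mesh(1, c(0.5, 0.5, 0.5)))
  halves <- plane_split(cu, plane3(c(0.5, 0.5, 0.5), c(0, 0, 1)))
  expect_false(halves$missed)
  expect_equal(mesh_stats(halves$upper)$volume, 0.5, tolerance = 0.01)
  expect_equal(mesh_stats(halves$lower)$volume, 0.5, tolerance = 0.01)

  sp <- solid_part(sphere_mesh(10, 4), "ball")
  v0 <- mesh_stats(sp)$volume
  hs <- plane_split(sp)  # default: horizontal centroid plane
  vu <- mesh_stats(hs$upper)$volume
  vl <- mesh_stats(hs$lower)$volume
  expect_equal(vu, vl, tolerance = 0.01)
  expect_equal(vu + vl, v0, tolerance = 0.01)
  expect_true(mesh_stats(hs$upper)$watertight)
  expect_true(mesh_stats(hs$lower)$watertight)

  # near-tangent plane: a small cap plus the bulk still sum to the total
  hc <- plane_split(sp, plane3(c(0, 0, 8)))
  expect_equal(mesh_stats(hc$upper)$volume + mesh_stats(hc$lower)$volume,
               v0, tolerance = 0.01)
  expect_lt(mesh_stats(hc$upper)$volume, 0.05 * v0)

  # plane missing the part entirely
  miss <- plane_split(sp, plane3(c(0, 0, 50)))
  expect_true(miss$missed)
  expect_null(miss$lower)
})

test_that("clearance subtraction carves an analytically sized cavity", {
  host <- solid_part(cube_mesh(20), "host")
  ins <- solid_part(cube_mesh(10), "insert")
  res <- subtract_insert(host, ins, clearance = 1)
  expect_true(mesh_stats(res)$watertight)
  expect_equal(mesh_stats(res)$volume, 8000 - 12^3, tolerance = 0.02)
  # clearance -> 0 approaches the plain Boolean difference
  res0 <- subtract_insert(host, ins, clearance = 0.01)
  expect_equal(mesh_stats(res0)$volume, 8000 - 1000, tolerance = 0.02)
  # insert fully outside: host unchanged in volume
  far <- solid_part(cube_mesh(4, c(30, 0, 0)), "far")
  resf <- subtract_insert(host, far, clearance = 0.5)
  expect_equal(mesh_stats(resf)$volume, 8000, tolerance = 0.02)
  expect_error(subtract_insert(host, ins, clearance = 0), "clearance")
  holed <- surface_mesh(ins$vertices, ins$faces[-1, ], unit = "mm")
  expect_error(subtract_insert(host, holed, clearance = 1), "watertight")
})

test_that("host volume decreases strictly with clearance", {
  host <- solid_part(cube_mesh(20), "host")
  ins <- solid_part(cube_mesh(10), "insert")
  vols <- vapply(c(0.5, 1, 1.5), function(cl)
    mesh_stats(subtract_insert(host, ins, clearance = cl))$volume,
    numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("fit verification reports gaps and interpenetration", {
  host <- solid_part(cube_mesh(20), "host")
  ins <- solid_part(cube_mesh(10), "insert")
  carved <- subtract_insert(host, ins, clearance = 1)
  fit <- verify_fit(carved, ins, clearance = 1)
  expect_true(fit$pass)
  expect_equal(fit$intersection_volume, 0)
  expect_equal(fit$min_gap, 1, tolerance = 0.3)
  # insert translated against the cavity wall: touching but no overlap
  shifted <- solid_part(cube_mesh(10, c(0.99, 0, 0)), "shifted")
  fit2 <- verify_fit(carved, shifted, clearance = 1)
  expect_lt(fit2$min_gap, 0.3)
  expect_true(fit2$pass)
  # oversized insert interpenetrates: fail
  big <- solid_part(cube_mesh(15), "big")
  fit3 <- verify_fit(carved, big, clearance = 1)
  expect_gt(fit3$intersection_volume, 0)
  expect_false(fit3$pass)
})

test_that("assemblies apply splits then fits and emit one STL per part", {
  dir <- withr::local_tempdir()
  host <- solidify(sphere_mesh(12, 3), 1, "filled", name = "surface")
  nuc <- solid_part(sphere_mesh(5, 3), "nucleus", "blue")
  asm <- build_assembly(
    list(surface = host, nucleus = nuc),
    splits = list(list(part = "surface", plane = NULL)),
    fits = list(list(host = "surface", insert = "nucleus",
                     clearance = 0.3)),
    dir = dir, model = "toy")
  expect_length(asm$parts, 3L)  # 2 initial parts + 1 split
  expect_length(asm$files, 3L)
  expect_true(all(file.exists(asm$files)))
  man <- jsonlite::read_json(asm$manifest)
  expect_length(man$parts, 3L)
  for (p in asm$parts) {
    st <- mesh_stats(p)
    expect_true(st$watertight)
    expect_gt(st$volume, 0)
  }
  # the fitted nucleus does not intersect either carved half
  for (half in c("surface_upper", "surface_lower")) {
    fit <- verify_fit(asm$parts[[half]], asm$parts$nucleus, 0.3)
    expect_equal(fit$intersection_volume, 0,
                 tolerance = 0.01 * mesh_stats(nuc)$volume)
  }
  expect_error(build_assembly(list(a = host, a = nuc)), "uniquely named")
})
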