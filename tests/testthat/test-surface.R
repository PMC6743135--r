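test_that("mesh metrics report volume, area, watertightness, components", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  m <- mesh_metrics(cube)
  expect_equal(m$volume_mm3, 1)
  expect_equal(m$area_mm2, 6)
  expect_true(m$watertight)
  expect_equal(m$n_components, 1)
  expect_equal(m$euler_characteristic, 2)

  holed <- surface_mesh(cube$vertices, cube$faces[-1, ])
  expect_false(mesh_metrics(holed)$watertight)

  two <- surface_mesh(rbind(cube$vertices, cube$vertices + 5),
                      rbind(cube$faces, cube$faces + 8L))
  expect_equal(mesh_metrics(two)$n_components, 2)
})

test_that("extract_surface of a voxel sphere is watertight and accurate", {
  vol <- voxelize_mesh(mesh_icosphere(10, 3), 0.5)
  surf <- extract_surface(vol)
  m <- mesh_metrics(surf)
  expect_true(m$watertight)
  expect_equal(m$n_components, 1)
  expect_equal(m$euler_characteristic, 2)
  expect_equal(m$volume_mm3, 4 / 3 * pi * 1000, tolerance = 0.02)
  # surface volume is exactly the voxel volume
  expect_equal(m$volume_mm3, volume_of(vol), tolerance = 1e-12)
})

test_that("a single voxel extracts to its bounding cuboid", {
  g <- array(FALSE, c(3, 3, 3)); g[2, 2, 2] <- TRUE
  vol <- label_volume(g, c(0.4, 0.5, 0.6), c(0, 0, 0))
  m <- mesh_metrics(extract_surface(vol))
  expect_equal(m$volume_mm3, 0.4 * 0.5 * 0.6, tolerance = 1e-12)
  expect_true(m$watertight)
})

test_that("disconnected occupancy keeps the largest component with warning", {
  g <- array(FALSE, c(12, 6, 6))
  g[2:5, 2:5, 2:5] <- TRUE   # 64 voxels
  g[8:10, 2:4, 2:4] <- TRUE  # 27 voxels
  vol <- label_volume(g, rep(1, 3), c(0, 0, 0))
  expect_warning(surf <- extract_surface(vol), "2 connected components")
  expect_equal(mesh_metrics(surf)$volume_mm3, 64)
})

test_that("reconstruction error decreases with voxel spacing", {
  ico <- mesh_icosphere(10, 3)
  err <- vapply(c(1, 0.25), function(sp) {
    abs(mesh_metrics(extract_surface(voxelize_mesh(ico, sp)))$volume_mm3 -
          4 / 3 * pi * 1000)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("checkerboard voxel patterns still give a watertight surface", {
  g <- array(FALSE, c(4, 4, 4))
  g[2, 2, 2] <- TRUE; g[3, 3, 2] <- TRUE  # edge-touching diagonal pair
  vol <- label_volume(g, rep(1, 3), c(0, 0, 0))
  surf <- extract_surface(vol)
  expect_true(mesh_metrics(surf)$watertight)
})

test_that("smoothing with factor 0 is the identity", {
  surf <- extract_surface(voxelize_mesh(mesh_icosphere(5, 2), 0.5))
  out <- smooth_surface(surf, smoothing_spec(0))
  expect_identical(out$vertices, surf$vertices)
  expect_identical(out$faces, surf$faces)
})

test_that("Taubin smoothing shrinks area, conserves volume and topology", {
  surf <- extract_surface(voxelize_mesh(mesh_icosphere(10, 3), 0.5))
  m0 <- mesh_metrics(surf)
  sm <- smooth_surface(surf, smoothing_spec(0.5))
  m1 <- mesh_metrics(sm)
  expect_lt(m1$area_mm2, m0$area_mm2)
  expect_equal(m1$volume_mm3, m0$volume_mm3, tolerance = 0.05)
  expect_true(m1$watertight)
  expect_equal(m1$n_components, m0$n_components)
  expect_equal(m1$euler_characteristic, m0$euler_characteristic)
  # more smoothing never increases area
  m2 <- mesh_metrics(smooth_surface(surf, smoothing_spec(1)))
  expect_lte(m2$area_mm2, m1$area_mm2)
})

test_that("smoothing refuses non-watertight input and bad factors", {
  cube <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  holed <- surface_mesh(cube$vertices, cube$faces[-1, ])
  expect_error(smooth_surface(holed), "watertight")
  expect_error(smoothing_spec(1.5), "\\[0, 1\\]")
  expect_error(smoothing_spec(-0.1), "\\[0, 1\\]")
})
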