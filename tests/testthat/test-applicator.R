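test_that("the default base cylinder matches the analytic volume", {
  base <- make_base(base_spec())
  expect_equal(mesh_metrics(base)$volume_mm3, pi * 36 * 60,
               tolerance = 0.005)
  expect_true(mesh_metrics(base)$watertight)
  expect_error(base_spec(length = 0), "> 0")
  # doubling the tessellation at least halves the volume error
  e1 <- abs(mesh_metrics(make_base(base_spec(), 64))$volume_mm3 - pi * 2160)
  e2 <- abs(mesh_metrics(make_base(base_spec(), 128))$volume_mm3 - pi * 2160)
  expect_lte(e2, e1 / 2)
})

test_that("voxel union of overlapping cubes has the analytic volume", {
  a <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  b <- mesh_box(c(0, 0, 0.5), c(1, 1, 1.5))
  merged <- merge_base_and_template(a, b, pitch = 0.05)
  expect_equal(mesh_metrics(merged)$volume_mm3, 1.5, tolerance = 0.05)
  same <- merge_base_and_template(a, a, pitch = 0.05)
  expect_equal(mesh_metrics(same)$volume_mm3, 1, tolerance = 0.05)
  va <- mesh_metrics(merged)$volume_mm3
  expect_lte(va, 2)
  expect_gte(va, 1)
})

test_that("disjoint solids refuse to merge", {
  a <- mesh_box(c(0, 0, 0), c(1, 1, 1))
  b <- mesh_box(c(5, 5, 5), c(6, 6, 6))
  expect_error(merge_base_and_template(a, b, pitch = 0.1),
               "does not contact")
})

test_that("loop joining validates the bridge curvature", {
  z <- seq(40, 0, by = -2)
  a <- channel_plan_from_samples("a", "intracavitary", cbind(-40, 0, z))
  b <- channel_plan_from_samples("b", "intracavitary", cbind(40, 0, z))
  phi <- seq(0, pi, length.out = 13)[2:12]
  loop <- make_loop_channel(a, b, cbind(-40 * cos(phi), 0, -40 * sin(phi)))
  expect_identical(loop$role, "loop")
  r_min <- attr(curvature_profile(loop), "r_min")
  expect_equal(r_min, 40, tolerance = 0.05)
  expect_true(validate_channels(loop)$pass)

  a30 <- channel_plan_from_samples("a", "intracavitary", cbind(-30, 0, z))
  b30 <- channel_plan_from_samples("b", "intracavitary", cbind(30, 0, z))
  expect_warning(
    bad <- make_loop_channel(a30, b30,
                             cbind(-30 * cos(phi), 0, -30 * sin(phi))),
    "hard radius")
  expect_false(validate_channels(bad)$pass)
})

test_that("a carved loop has exactly two surface openings", {
  slab <- mesh_box(c(-25, -6, 0), c(25, 6, 25))
  zs <- seq(30, 12, by = -0.5)
  a <- channel_plan_from_samples("a", "intracavitary", cbind(-10, 0, zs))
  b <- channel_plan_from_samples("b", "intracavitary", cbind(10, 0, zs))
  phi <- seq(0, pi, length.out = 19)[2:18]
  loop <- make_loop_channel(a, b, cbind(-10 * cos(phi), 0,
                                        12 - 10 * sin(phi)), r_hard = 0)
  vol <- voxelize_mesh(slab, 0.25)
  res <- applicatr:::carve_grid(vol, loop, enforce_constraint = FALSE,
                                record_tube = TRUE)
  outside <- res$tube$grid & !vol$grid
  n_open <- applicatr:::cc_label3d(as.vector(outside),
                                   dim(outside))$n_components
  expect_equal(n_open, 2)
})

test_that("a three-channel applicator builds watertight with six openings", {
  topo <- synth_topography(topography_params(semi_axes = c(20, 17),
                                             apex_depth = 32))
  surf <- smooth_surface(extract_surface(voxelize(topo, "vault", 0.8)), 0.5)
  wps <- synth_waypoints(3, topo, "pass", seed = 2, z_start = -70)
  plans <- lapply(wps, fit_spline)
  design <- applicator_design(surf, base_spec(anchor = c(0, 0, 3)), plans,
                              pitch = 0.4)
  build <- build_applicator(design)
  expect_true(build$metrics$watertight)
  expect_equal(build$metrics$n_components, 1)
  expect_equal(nrow(build$report), 3)
  expect_equal(sum(build$report$openings), 6)
  expect_true(all(build$report$r_min >= 35))
})

test_that("zero channels reduces the build to the union", {
  topo <- synth_topography(topography_params(semi_axes = c(16, 14),
                                             apex_depth = 24))
  surf <- extract_surface(voxelize(topo, "vault", 0.8))
  base <- base_spec(length = 30, anchor = c(0, 0, 3))
  design <- applicator_design(surf, base, list(), pitch = 0.4)
  build <- build_applicator(design)
  merged <- merge_base_and_template(surf, make_base(base), pitch = 0.4)
  expect_equal(build$solid_volume_mm3, mesh_metrics(merged)$volume_mm3,
               tolerance = 0.01)
})

test_that("an invalid channel aborts the build before carving", {
  topo <- synth_topography(topography_params(semi_axes = c(16, 14),
                                             apex_depth = 24))
  surf <- extract_surface(voxelize(topo, "vault", 0.8))
  bad <- arc_plan(25, span_deg = 90, label = "bad")
  design <- applicator_design(surf, base_spec(anchor = c(0, 0, 3)),
                              list(bad), pitch = 0.4)
  expect_error(build_applicator(design), "validation failed.*bad")
})
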