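test_that("collinear waypoints give a straight channel", {
  plan <- fit_spline(waypoint_list("s", rbind(c(0, 0, 0), c(0, 0, 10),
                                              c(0, 0, 30))))
  expect_lt(max(abs(plan$samples[, 1:2])), 1e-9)
  expect_identical(attr(curvature_profile(plan), "r_min"), Inf)
  # two waypoints: exact straight segment
  p2 <- fit_spline(waypoint_list("s2", rbind(c(0, 0, 0), c(3, 4, 0))))
  expect_equal(p2$arc_length, 5, tolerance = 1e-9)
})

test_that("spline through four waypoints on a 60 mm circle stays within 0.1 mm", {
  th <- seq(0, pi / 2, length.out = 4)
  wp <- waypoint_list("arc", cbind(60 * cos(th), 60 * sin(th), 0))
  plan <- fit_spline(wp)
  dev <- abs(sqrt(plan$samples[, 1]^2 + plan$samples[, 2]^2) - 60)
  expect_lt(max(dev), 0.1)
  # the spline interpolates every waypoint
  at_wp <- plan$spline_eval(plan$knots)
  expect_lt(max(abs(at_wp - wp$points)), 1e-6)
})

test_that("resampling is uniform and converges with the step", {
  th <- seq(0, pi / 2, length.out = 6)
  wp <- waypoint_list("arc", cbind(40 * cos(th), 40 * sin(th), 0))
  plan <- fit_spline(wp, sample_step = 0.5)
  seg <- sqrt(rowSums(diff(plan$samples)^2))
  expect_lt(diff(range(seg)) / mean(seg), 0.01)
  plan2 <- fit_spline(wp, sample_step = 0.25)
  expect_lt(abs(plan2$arc_length - plan$arc_length) / plan$arc_length, 0.001)
})

test_that("curvature of exact circle samples is the circle radius", {
  phi <- seq(0, pi / 2, by = pi / 180)  # 1 degree spacing
  samples <- cbind(35 * cos(phi), 35 * sin(phi), 0)
  prof <- curvature_profile(samples)
  expect_lt(max(abs(prof$r - 35)), 1e-3)
  expect_equal(attr(prof, "r_min"), 35, tolerance = 1e-6)
  expect_equal(nrow(prof), nrow(samples) - 2)
})

test_that("helix curvature matches the closed form", {
  t <- seq(0, 4 * pi, by = 0.01)
  hel <- cbind(30 * cos(t), 30 * sin(t), 20 * t)
  prof <- curvature_profile(hel)
  expect_equal(max(abs(prof$r - (30^2 + 20^2) / 30)), 0, tolerance = 1e-2)
})

test_that("curvature oracle holds for random radii (property)", {
  withr::with_seed(11, {
    for (i in 1:20) {
      R <- runif(1, 10, 200)
      phi <- seq(0, pi / 2, by = pi / 180)
      samples <- cbind(R * cos(phi), R * sin(phi), 0)
      r_min <- attr(curvature_profile(samples), "r_min")
      expect_lt(abs(r_min - R) / R, 1e-3)
    }
  })
})

test_that("sampling refinement cannot degrade circle curvature estimates", {
  # on exact circle samples the circumradius estimator is exact at any
  # sampling density
  for (step in c(2, 1, 0.5)) {
    plan <- arc_plan(50, span_deg = 90, step = step)
    expect_lt(abs(attr(curvature_profile(plan), "r_min") - 50), 1e-9)
  }
  # on fitted splines, the discrete estimate converges as the step halves
  th <- seq(0, pi / 2, length.out = 8)
  wp <- waypoint_list("arc", cbind(50 * cos(th), 50 * sin(th), 0))
  r <- vapply(c(1, 0.5, 0.25, 0.125), function(st) {
    attr(curvature_profile(fit_spline(wp, sample_step = st)), "r_min")
  }, numeric(1))
  expect_lt(abs(r[4] - r[3]), abs(r[2] - r[1]))
})

test_that("fewer than three samples means a straight profile", {
  prof <- curvature_profile(rbind(c(0, 0, 0), c(0, 0, 10)))
  expect_identical(attr(prof, "r_min"), Inf)
  expect_equal(nrow(prof), 0)
})
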