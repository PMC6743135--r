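test_that("unperturbed vault volume matches the half-ellipsoid", {
  params <- topography_params(amplitudes = numeric(0))
  topo <- synth_topography(params)
  vol <- voxelize(topo, "vault", 0.5)
  expect_equal(volume_of(vol), 2 / 3 * pi * 25 * 20 * 40, tolerance = 0.05)
})

test_that("topography is deterministic per seed and simple at the limit", {
  expect_identical(synth_topography(topography_params(seed = 4)),
                   synth_topography(topography_params(seed = 4)))
  params <- topography_params(amplitudes = c(0.14, 0.1, 0.05))
  topo <- synth_topography(params)
  for (slice in topo$structures$vault) {
    # star-shaped about the origin: radius strictly positive and single
    # angular branch implies a simple polygon
    r <- sqrt(slice[, 1]^2 + slice[, 2]^2)
    expect_true(all(r > 0))
    ang <- atan2(slice[, 2], slice[, 1])
    expect_true(all(diff(sort(ang)) > 0))
  }
})

test_that("waypoint generation hits the requested curvature band", {
  topo <- synth_topography(topography_params())
  for (mode in c("pass", "advisory", "fail")) {
    wps <- synth_waypoints(2, topo, mode, seed = 3)
    report <- validate_channels(lapply(wps, fit_spline))
    if (mode == "pass") {
      expect_true(all(report$pass))
      expect_false(any(report$advisory))
    } else if (mode == "advisory") {
      expect_true(all(report$pass))
      expect_true(all(report$advisory))
    } else {
      expect_false(any(report$pass))
    }
  }
})

test_that("noise-free traces are calibrated to the buckling analysis", {
  p <- force_model_params(noise_sd = 0, phantom_sd = 0)
  t35 <- synth_force_trace(35, "blunt", p)
  expect_equal(max(t35$force_N), 14, tolerance = 0.01)
  expect_equal(t35$depth_mm[which.max(t35$force_N)], 50, tolerance = 1)
  t75 <- synth_force_trace(75, "blunt", p)
  expect_equal(max(t75$force_N), 2 + 420 / 75, tolerance = 0.01)
  # post-exit slope equals the tissue slope
  tail_idx <- t75$depth_mm >= 90
  slope <- coef(lm(force_N ~ depth_mm, t75[tail_idx, ]))[2]
  expect_equal(unname(slope), p$tissue_slope, tolerance = 1e-9)
})

test_that("the synthetic dataset recovers the generator's peak law", {
  radii <- seq(35, 75, 10)
  design <- randomize_design(radii, phantoms = 5, reps = 1, seed = 11)
  params <- force_model_params()
  ds <- synth_force_dataset(design, params, seed = 12)
  expect_equal(nrow(ds), nrow(design) * (params$max_depth /
                                           params$depth_step + 1))
  # recovery is about the generator and estimator, so no buckling
  # screening: excluding threshold crossers would truncate the r = 35
  # group
  sm <- summarize_insertions(filter_forces(ds), buckling_threshold = Inf)
  by_r <- sm |>
    dplyr::group_by(.data$radius_mm) |>
    dplyr::summarise(mean_peak = mean(.data$peak_N),
                     se = stats::sd(.data$peak_N) / sqrt(dplyr::n()))
  expected <- peak_force(by_r$radius_mm, params)
  # phantom intercepts shift every radius equally, so compare the
  # radius-effect contrasts (deviation from the grand mean) within 2
  # standard errors, and bound the common shift by the intercept spread
  obs_dev <- by_r$mean_peak - mean(by_r$mean_peak)
  exp_dev <- expected - mean(expected)
  expect_true(all(abs(obs_dev - exp_dev) <= 2 * by_r$se + 0.05))
  expect_lt(abs(mean(by_r$mean_peak - expected)),
            3 * params$phantom_sd / sqrt(5) + 0.05)
})

test_that("sub-limit radii buckle; generation is seed-deterministic", {
  p <- force_model_params(noise_sd = 0, phantom_sd = 0)
  t30 <- synth_force_trace(30, "blunt", p)
  s <- summarize_insertion(t30$depth_mm, zero_phase_ma(t30$force_N, 20))
  expect_true(s$buckled)
  expect_equal(peak_force(30), 16, tolerance = 1e-12)

  d <- randomize_design(c(40, 60), phantoms = 2, reps = 1, seed = 5)
  expect_identical(synth_force_dataset(d, seed = 6),
                   synth_force_dataset(d, seed = 6))
})

test_that("force traces round-trip through delimited text", {
  tr <- synth_force_trace(50, "sharp", force_model_params(noise_sd = 0),
                          phantom = 2, rep = 3)
  tr <- tr[seq(1, nrow(tr), by = 50), ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_force_traces(tr, path)
  back <- read_force_traces(path)
  expect_equal(back$force_N, tr$force_N, tolerance = 1e-9)
  expect_identical(back$tip, tr$tip)
})
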