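triangle_trace <- function(peak, peak_depth = 42, max_depth = 80,
                           step = 0.1) {
  d <- seq(0, max_depth, by = step)
  f <- peak * pmax(0, 1 - abs(d - peak_depth) / peak_depth)
  list(depth = d, force = f)
}

test_that("a 13 N peak does not buckle, a 15 N peak does", {
  t13 <- triangle_trace(13)
  s13 <- summarize_insertion(t13$depth, t13$force)
  expect_false(s13$buckled)
  expect_true(is.na(s13$abort_depth_mm))
  expect_equal(s13$peak_N, 13, tolerance = 1e-9)

  t15 <- triangle_trace(15, peak_depth = 42)
  s15 <- summarize_insertion(t15$depth, t15$force)
  expect_true(s15$buckled)
  # first crossing of 14 N on the rising flank, before the 42 mm peak
  expect_lt(s15$abort_depth_mm, 42)
  expect_gt(s15$abort_depth_mm, 35)
  # statistics stop at the abort depth
  expect_lte(s15$peak_N, 14.1)
})

test_that("summary quartiles are ordered and the peak depth is right", {
  t <- triangle_trace(10, peak_depth = 50)
  s <- summarize_insertion(t$depth, t$force)
  expect_lte(s$q25_N, s$median_N)
  expect_lte(s$median_N, s$q75_N)
  expect_lte(s$q75_N, s$peak_N)
  expect_equal(s$peak_depth_mm, 50, tolerance = 0.2)
  expect_true(s$peak_in_applicator)
})

test_that("the buckling decision boundary sits at 14 N (bisection)", {
  base <- triangle_trace(1, peak_depth = 45)
  decision <- function(peak) {
    summarize_insertion(base$depth, peak * base$force)$buckled
  }
  lo <- 10; hi <- 20
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (decision(mid)) hi <- mid else lo <- mid
  }
  expect_equal((lo + hi) / 2, 14, tolerance = 0.01 / 14)
})

test_that("degenerate traces are rejected", {
  expect_error(summarize_insertion(numeric(0), numeric(0)), "empty")
  expect_error(summarize_insertion(c(0, 1), c(1, 2, 3)), "same length")
  expect_error(summarize_insertion(c(1, 0), c(1, 2)), "monotone")
})

test_that("mean force curves average identical traces to the trace", {
  p <- force_model_params(noise_sd = 0)
  tr <- dplyr::bind_rows(
    synth_force_trace(50, "blunt", p, phantom = 1, rep = 1),
    synth_force_trace(50, "blunt", p, phantom = 2, rep = 1))
  curves <- mean_force_curves(tr, depth_step = 0.5)
  one <- synth_force_trace(50, "blunt", p)
  ref <- approx(one$depth_mm, one$force_N, xout = curves$depth_mm)$y
  expect_equal(curves$mean_force_N, ref, tolerance = 1e-9)
})

test_that("peak force ordering is monotone in radius; peaks sit near 50 mm", {
  p <- force_model_params(noise_sd = 0)
  tr <- dplyr::bind_rows(lapply(seq(35, 75, by = 10), function(r) {
    synth_force_trace(r, "blunt", p, phantom = 1, rep = 1)
  }))
  tr$force_N <- unlist(tapply(tr$force_N, tr$radius_mm, zero_phase_ma,
                              kernel = 20))
  curves <- mean_force_curves(tr)
  peaks <- attr(curves, "peaks")
  peaks <- peaks[order(peaks$radius_mm), ]
  expect_true(all(diff(peaks$peak_N) < 0))
  expect_true(all(abs(peaks$peak_depth_mm - 50) <= 1))
})
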