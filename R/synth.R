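#' Synthetic vault topography parameters
#'
#' Parameters of the synthetic gel-distended vaginal vault: a stack of
#' planar closed contours shrinking from an elliptical base to an apex
#' (half-ellipsoid envelope), perturbed by up to three low-order
#' angular harmonics so the contours stay simple and star-shaped.
#'
#' @param semi_axes Base ellipse semi-axes (mm).
#' @param apex_depth Vault depth from base plane to apex (mm).
#' @param amplitudes Relative harmonic amplitudes (modes 1..3); their
#'   sum must stay below 0.3 so contours remain simple.
#' @param slice_spacing Contour slice spacing (mm).
#' @param n_vertices Vertices per contour polygon.
#' @param seed Seed for the harmonic phases.
#' @return A `topography_params` object.
#' @export
topography_params <- function(semi_axes = c(25, 20), apex_depth = 40,
                              amplitudes = c(0.06, 0.04, 0.02),
                              slice_spacing = 2, n_vertices = 90,
                              seed = 1) {
  if (length(amplitudes) > 3) abort("at most 3 harmonic modes")
  if (sum(abs(amplitudes)) >= 0.3)
    abort("harmonic amplitudes must sum below 30% of the radius")
  if (slice_spacing <= 0) abort("slice_spacing must be > 0")
  structure(list(semi_axes = semi_axes, apex_depth = apex_depth,
                 amplitudes = amplitudes, slice_spacing = slice_spacing,
                 n_vertices = n_vertices, seed = seed),
            class = "topography_params")
}

#' Generate a synthetic vault contour stack
#'
#' Stands in for a patient MRI segmentation: closed, simple,
#' star-shaped contours tapering to an apex, deterministic per seed.
#'
#' @param params A [topography_params()].
#' @return A [contour_set()] with one structure `"vault"`.
#' @export
synth_topography <- function(params = topography_params()) {
  stopifnot(inherits(params, "topography_params"))
  a <- params$semi_axes[1]; b <- params$semi_axes[2]
  depth <- params$apex_depth
  phases <- withr::with_seed(params$seed,
                             runif(length(params$amplitudes), 0, 2 * pi))
  th <- seq(0, 2 * pi, length.out = params$n_vertices + 1)[-1]
  r_ell <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  pert <- rep(1, length(th))
  for (m in seq_along(params$amplitudes)) {
    pert <- pert + params$amplitudes[m] * cos(m * th + phases[m])
  }
  zs <- seq(0, depth, by = params$slice_spacing)
  scale <- sqrt(pmax(1 - (zs / depth)^2, 0))
  keep <- scale * min(a, b) * (1 - sum(abs(params$amplitudes))) >= 1
  zs <- zs[keep]; scale <- scale[keep]
  slices <- purrr::map2(zs, scale, function(z, sc) {
    r <- sc * r_ell * pert
    cbind(r * cos(th), r * sin(th), z)
  })
  contour_set(list(vault = slices), frame_of_reference = "1.2.826.0.1.999.1")
}

#' Synthetic channel waypoints with a prescribed curvature band
#'
#' Generates waypoint sets whose fitted splines fall in a requested
#' radius-of-curvature band: straight through the base, then a circular
#' bend rising through the vault until it exits the topography. Each
#' candidate is verified with [fit_spline()] and [curvature_profile()]
#' before being returned; generation retries (up to 100 times per
#' channel) until the band is met.
#'
#' @param n_channels Number of channels.
#' @param topography A [contour_set()] from [synth_topography()].
#' @param mode `"pass"` (r_min >= 50), `"advisory"` (35 <= r_min < 50)
#'   or `"fail"` (r_min < 35).
#' @param seed Integer seed.
#' @param z_start Channel start below the base (mm).
#' @param bundle_radius Radial offset of channel starts inside the base
#'   (mm).
#' @return List of [waypoint_list()] objects (roles interstitial).
#' @export
synth_waypoints <- function(n_channels, topography,
                            mode = c("pass", "advisory", "fail"),
                            seed = 1, z_start = -70, bundle_radius = 2.2) {
  mode <- match.arg(mode)
  stopifnot(inherits(topography, "contour_set"))
  pts <- do.call(rbind, topography$structures[[1]])
  depth <- max(pts[, 3])
  r_out <- max(sqrt(pts[, 1]^2 + pts[, 2]^2))
  band <- switch(mode,
                 pass = c(60, 85), advisory = c(38, 46), fail = c(22, 32))
  check <- switch(mode,
                  pass = function(r) r >= 50,
                  advisory = function(r) r >= 35 && r < 50,
                  fail = function(r) r < 35)
  withr::with_seed(seed, {
    lapply(seq_len(n_channels), function(j) {
      psi <- 2 * pi * (j - 1) / n_channels + runif(1, -0.1, 0.1)
      u <- c(cos(psi), sin(psi), 0)
      start_xy <- bundle_radius * u
      for (attempt in 1:100) {
        R <- runif(1, band[1], band[2])
        phi <- seq(0, 100 * pi / 180, by = 10 * pi / 180)
        arc <- t(sapply(phi, function(ph) {
          start_xy + R * (1 - cos(ph)) * u + c(0, 0, R * sin(ph))
        }))
        outside <- arc[, 3] > depth + 5 |
          sqrt(arc[, 1]^2 + arc[, 2]^2) > r_out + 5
        stop_i <- if (any(outside)) which(outside)[1] else length(phi)
        arc <- arc[seq_len(stop_i), , drop = FALSE]
        wp_pts <- rbind(start_xy + c(0, 0, z_start),
                        start_xy + c(0, 0, z_start / 2),
                        arc)
        wp <- waypoint_list(sprintf("needle_%02d_int", j), wp_pts,
                            role = "interstitial")
        plan <- fit_spline(wp)
        r_min <- attr(curvature_profile(plan), "r_min")
        if (check(r_min)) return(wp)
      }
      abort(paste0("could not generate a '", mode,
                   "' channel within 100 attempts"))
    })
  })
}

#' Synthetic insertion-force model parameters
#'
#' The friction-dominated force model behind the synthetic traces: the
#' in-channel force rises smoothly to a peak `baseline + friction / r`
#' at the applicator exit depth, then drops by a fixed fraction and
#' grows linearly with the tissue-cutting slope. Defaults are
#' calibrated so the peak at the 35 mm radius limit is
#' `2 + 420 / 35 = 14` N, the buckling level, at a 50 mm exit depth.
#' The tip effect defaults to 0 N (no mean difference between blunt and
#' sharp tips); set it nonzero for power studies.
#'
#' @param baseline Baseline force a (N).
#' @param friction_coeff Friction coefficient b (N mm): peak is
#'   `a + b / r`.
#' @param tissue_slope Post-exit tissue-cutting slope (N/mm).
#' @param exit_depth Applicator exit depth (mm).
#' @param noise_sd Additive per-sample Gaussian noise sd (N).
#' @param phantom_sd Phantom-level random intercept sd (N).
#' @param rep_sd Insertion-level random intercept sd (N).
#' @param tip_effect Mean force offset of the sharp tip (N).
#' @param drop_fraction Fractional force drop after the peak.
#' @param rise_sigma,drop_sigma Widths (mm) of the smooth rise to the
#'   peak and of the post-peak drop.
#' @param depth_step Depth sampling step (mm; 0.05 mm = 100 Hz at the 5
#'   mm/s insertion speed).
#' @param max_depth Trace length (mm).
#' @param speed Insertion speed (mm/s).
#' @return A `force_model_params` object.
#' @export
force_model_params <- function(baseline = 2, friction_coeff = 420,
                               tissue_slope = 0.05, exit_depth = 50,
                               noise_sd = 0.3, phantom_sd = 0.2,
                               rep_sd = 0, tip_effect = 0,
                               drop_fraction = 0.35, rise_sigma = 12,
                               drop_sigma = 3, depth_step = 0.05,
                               max_depth = 100, speed = 5) {
  stopifnot(baseline >= 0, friction_coeff >= 0, tissue_slope >= 0,
            noise_sd >= 0, phantom_sd >= 0, rep_sd >= 0)
  structure(list(baseline = baseline, friction_coeff = friction_coeff,
                 tissue_slope = tissue_slope, exit_depth = exit_depth,
                 noise_sd = noise_sd, phantom_sd = phantom_sd,
                 rep_sd = rep_sd, tip_effect = tip_effect,
                 drop_fraction = drop_fraction, rise_sigma = rise_sigma,
                 drop_sigma = drop_sigma, depth_step = depth_step,
                 max_depth = max_depth, speed = speed),
            class = "force_model_params")
}

#' @describeIn force_model_params Noise-free peak force for a channel
#'   radius.
#' @param radius_mm Channel radius (mm).
#' @param params A `force_model_params`.
#' @export
peak_force <- function(radius_mm, params = force_model_params()) {
  params$baseline + params$friction_coeff / radius_mm
}

#' Generate one synthetic force-depth trace
#'
#' @param radius_mm Channel radius of curvature (mm), > 0.
#' @param tip `"blunt"` or `"sharp"`.
#' @param params A [force_model_params()].
#' @param seed Optional seed for the noise (otherwise the current RNG
#'   stream is used).
#' @param phantom,rep Metadata carried into the output.
#' @param offset Additional force offset (phantom/insertion intercepts),
#'   N.
#' @return A tibble with `depth_mm`, `force_N`, `radius_mm`, `tip`,
#'   `phantom`, `rep`.
#' @export
synth_force_trace <- function(radius_mm, tip = "blunt",
                              params = force_model_params(), seed = NULL,
                              phantom = NA_integer_, rep = NA_integer_,
                              offset = 0) {
  if (radius_mm <= 0) abort("radius must be > 0")
  d <- seq(0, params$max_depth, by = params$depth_step)
  pk <- peak_force(radius_mm, params) + offset +
    if (identical(tip, "sharp")) params$tip_effect else 0
  ex <- params$exit_depth
  f <- ifelse(
    d <= ex,
    pk * exp(-(d - ex)^2 / (2 * params$rise_sigma^2)),
    pk * ((1 - params$drop_fraction) +
            params$drop_fraction * exp(-(d - ex)^2 /
                                         (2 * params$drop_sigma^2))) +
      params$tissue_slope * (d - ex))
  add_noise <- function(v) {
    if (params$noise_sd > 0) v + rnorm(length(v), 0, params$noise_sd) else v
  }
  f <- if (!is.null(seed)) withr::with_seed(seed, add_noise(f))
       else add_noise(f)
  tibble::tibble(depth_mm = d, force_N = f, radius_mm = radius_mm,
                 tip = tip, phantom = phantom, rep = rep)
}

#' Generate the full synthetic force dataset for a design
#'
#' One trace per design row, with phantom-level and insertion-level
#' Gaussian intercepts on top of the per-sample noise; deterministic
#' per seed.
#'
#' @param design Design tibble from [randomize_design()].
#' @param params A [force_model_params()].
#' @param seed Integer seed.
#' @return Long tibble of traces (one row per depth sample).
#' @export
synth_force_dataset <- function(design, params = force_model_params(),
                                seed = 1) {
  stopifnot(all(c("phantom", "radius_mm", "tip", "rep") %in% names(design)))
  withr::with_seed(seed, {
    phantom_ids <- sort(unique(design$phantom))
    intercepts <- setNames(rnorm(length(phantom_ids), 0, params$phantom_sd),
                           phantom_ids)
    purrr::pmap_dfr(design[c("phantom", "radius_mm", "tip", "rep")],
                    function(phantom, radius_mm, tip, rep) {
      off <- intercepts[[as.character(phantom)]] +
        if (params$rep_sd > 0) rnorm(1, 0, params$rep_sd) else 0
      synth_force_trace(radius_mm, tip, params, seed = NULL,
                        phantom = phantom, rep = rep, offset = off)
    })
  })
}

#' Write or read force traces as delimited text
#'
#' Long-format tab-separated traces (`depth_mm`, `force_N` plus
#' metadata columns), the on-disk exchange format for measured or
#' synthetic force data.
#'
#' @param traces Long trace tibble.
#' @param path File path.
#' @return `write_force_traces()` returns `path` invisibly;
#'   `read_force_traces()` returns the tibble.
#' @export
write_force_traces <- function(traces, path) {
  readr::write_tsv(traces, path)
  invisible(path)
}

#' @rdname write_force_traces
#' @export
read_force_traces <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
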