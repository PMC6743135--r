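#' Summarise one needle insertion
#'
#' Computes the per-insertion summary statistics: force maximum, median,
#' 25th and 75th percentiles, and the depth of the maximum. A needle is
#' flagged as buckled when the (filtered) axial force strictly exceeds
#' the buckling threshold (about 14 N for 6F needles); the insertion is
#' treated as aborted at the first crossing, and the statistics cover
#' only the samples up to the abort depth.
#'
#' @param depth_mm,force_N Equal-length numeric vectors, depth monotone
#'   non-decreasing.
#' @param buckling_threshold Buckling force threshold in N (default 14).
#' @param exit_depth Applicator exit depth in mm (default 50), used to
#'   report whether the force peak occurred within the applicator.
#' @return A one-row tibble: `peak_N`, `peak_depth_mm`, `median_N`,
#'   `q25_N`, `q75_N`, `buckled`, `abort_depth_mm`,
#'   `peak_in_applicator`.
#' @export
summarize_insertion <- function(depth_mm, force_N, buckling_threshold = 14,
                                exit_depth = 50) {
  if (length(depth_mm) == 0 || length(force_N) == 0)
    abort("empty force trace")
  if (length(depth_mm) != length(force_N))
    abort("depth and force must have the same length")
  if (any(diff(depth_mm) < 0)) abort("depth must be monotone non-decreasing")
  over <- force_N > buckling_threshold
  buckled <- any(over)
  abort_depth <- if (buckled) depth_mm[which(over)[1]] else NA_real_
  keep <- if (buckled) seq_len(which(over)[1]) else seq_along(force_N)
  f <- force_N[keep]; d <- depth_mm[keep]
  q <- quantile(f, c(0.25, 0.5, 0.75), names = FALSE)
  tibble::tibble(
    peak_N = max(f),
    peak_depth_mm = d[which.max(f)],
    median_N = q[2], q25_N = q[1], q75_N = q[3],
    buckled = buckled,
    abort_depth_mm = abort_depth,
    peak_in_applicator = d[which.max(f)] <= exit_depth
  )
}

#' Summarise every insertion of a force-trace table
#'
#' @param traces Long tibble of (filtered) traces with `depth_mm`,
#'   `force_N` and insertion metadata columns (`phantom`, `radius_mm`,
#'   `tip`, `rep` as available).
#' @param buckling_threshold,exit_depth See [summarize_insertion()].
#' @return A tibble with one row per insertion: metadata plus the
#'   summary columns.
#' @export
summarize_insertions <- function(traces, buckling_threshold = 14,
                                 exit_depth = 50) {
  keys <- intersect(c("phantom", "radius_mm", "tip", "rep"), names(traces))
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$depth_mm, .by_group = TRUE) |>
    dplyr::group_modify(~ summarize_insertion(
      .x$depth_mm, .x$force_N, buckling_threshold, exit_depth)) |>
    dplyr::ungroup()
}

#' Mean force-depth curves per channel radius
#'
#' Resamples every trace onto a common depth grid (linear
#' interpolation, truncating to the common depth range with a warning
#' if ranges differ) and averages pointwise within each radius level.
#'
#' @param traces Long tibble of traces with `depth_mm`, `force_N`,
#'   `radius_mm` and insertion metadata.
#' @param depth_step Common grid step in mm.
#' @return A `force_curves` tibble (`radius_mm`, `depth_mm`,
#'   `mean_force_N`) with per-radius peak depths in attribute `"peaks"`.
#' @export
mean_force_curves <- function(traces, depth_step = 0.5) {
  stopifnot(all(c("depth_mm", "force_N", "radius_mm") %in% names(traces)))
  keys <- intersect(c("phantom", "radius_mm", "tip", "rep"), names(traces))
  ranges <- traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(lo = min(.data$depth_mm), hi = max(.data$depth_mm),
                     .groups = "drop")
  if (diff(range(ranges$lo)) > 1e-9 || diff(range(ranges$hi)) > 1e-9)
    warn("traces cover different depth ranges; truncating to the common range")
  grid <- seq(max(ranges$lo), min(ranges$hi), by = depth_step)
  resampled <- traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(.x, .y) {
      tibble::tibble(depth_mm = grid,
                     force_N = approx(.x$depth_mm, .x$force_N,
                                      xout = grid, ties = "ordered")$y)
    }) |>
    dplyr::ungroup()
  curves <- resampled |>
    dplyr::group_by(.data$radius_mm, .data$depth_mm) |>
    dplyr::summarise(mean_force_N = mean(.data$force_N), .groups = "drop")
  peaks <- curves |>
    dplyr::group_by(.data$radius_mm) |>
    dplyr::slice_max(.data$mean_force_N, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::rename(peak_N = "mean_force_N", peak_depth_mm = "depth_mm")
  structure(curves, peaks = peaks,
            class = c("force_curves", class(curves)))
}

#' @describeIn mean_force_curves Mean insertion force vs depth, one line
#'   per channel radius.
#' @param object A `force_curves` tibble.
#' @param ... Unused.
#' @export
autoplot.force_curves <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$depth_mm, y = .data$mean_force_N,
                               colour = factor(.data$radius_mm))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "insertion depth (mm)", y = "mean axial force (N)",
                  colour = "radius (mm)")
}
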