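#' Radius-of-curvature profile of a channel
#'
#' Discrete curvature along the uniform arc-length samples of a channel
#' plan: for each interior sample the radius is the circumradius of the
#' triangle formed with its two neighbours, `abc / (4 * area)`;
#' collinear triples give `Inf`. The estimator is independent of the
#' spline basis and exact on sampled circles.
#'
#' @param plan A `channel_plan` (see [fit_spline()]), or an n x 3 sample
#'   matrix.
#' @return A `curvature_profile` tibble with columns `s` (arc length mm,
#'   at interior samples) and `r` (radius mm), and attributes `r_min`
#'   and `s_at_min`.
#' @export
curvature_profile <- function(plan) {
  samples <- if (inherits(plan, "channel_plan")) plan$samples
             else as.matrix(plan)
  label <- if (inherits(plan, "channel_plan")) plan$label else ""
  n <- nrow(samples)
  if (n < 3) {
    out <- tibble::tibble(s = numeric(0), r = numeric(0))
    return(structure(out, r_min = Inf, s_at_min = NA_real_, label = label,
                     class = c("curvature_profile", class(out))))
  }
  p0 <- samples[1:(n - 2), , drop = FALSE]
  p1 <- samples[2:(n - 1), , drop = FALSE]
  p2 <- samples[3:n, , drop = FALSE]
  a <- sqrt(rowSums((p1 - p0)^2))
  b <- sqrt(rowSums((p2 - p1)^2))
  c_ <- sqrt(rowSums((p2 - p0)^2))
  cr <- cross3(p1 - p0, p2 - p0)
  area <- sqrt(rowSums(cr^2)) / 2
  r <- ifelse(area <= 1e-12 * a * b, Inf, a * b * c_ / (4 * area))
  seg <- sqrt(rowSums(diff(samples)^2))
  s <- cumsum(seg)[1:(n - 2)]
  r_min <- min(r)
  s_at_min <- if (is.finite(r_min)) s[which.min(r)] else NA_real_
  out <- tibble::tibble(s = s, r = r)
  structure(out, r_min = r_min, s_at_min = s_at_min, label = label,
            class = c("curvature_profile", class(out)))
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat("<curvature_profile>", attr(x, "label"), "r_min =",
      format(attr(x, "r_min"), digits = 6), "mm at s =",
      format(attr(x, "s_at_min"), digits = 6), "mm\n")
  NextMethod()
}

#' @describeIn curvature_profile Radius-of-curvature vs arc length plot
#'   with the hard and advisory limits marked.
#' @param object A `curvature_profile`.
#' @param r_hard,r_comfort Reference radii drawn as horizontal lines.
#' @param ... Unused.
#' @export
autoplot.curvature_profile <- function(object, r_hard = 35,
                                       r_comfort = 50, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = r_hard, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_hline(yintercept = r_comfort, linetype = "dotted",
                        colour = "orange") +
    ggplot2::coord_cartesian(ylim = c(0, min(200, max(df$r[is.finite(df$r)],
                                                      r_comfort * 2)))) +
    ggplot2::labs(x = "arc length (mm)", y = "radius of curvature (mm)",
                  title = attr(object, "label"))
}

#' Validate channel plans against radius-of-curvature constraints
#'
#' A channel passes iff its minimum radius of curvature is at least the
#' hard limit (35 mm by default, the radius below which needles jam or
#' buckle); channels passing with a minimum radius below the comfort
#' limit (50 mm) are flagged advisory, since friction forces there
#' degrade force feedback. Both boundaries are inclusive on the pass
#' side. The report is a pure function of the per-channel curvature
#' minima.
#'
#' @param plans A `channel_plan` or list of them.
#' @param r_hard Hard minimum radius (mm).
#' @param r_comfort Advisory comfort radius (mm).
#' @return A `channel_validation` tibble with one row per channel:
#'   `label`, `role`, `r_min`, `s_at_min`, `pass`, `advisory`,
#'   `span_start`, `span_end` (arc-length span where the radius is below
#'   the hard limit, NA if none).
#' @export
validate_channels <- function(plans, r_hard = 35, r_comfort = 50) {
  if (inherits(plans, "channel_plan")) plans <- list(plans)
  if (length(plans) == 0) abort("no channel plans supplied")
  eps <- 1e-6  # inclusive boundaries up to numerical noise
  rows <- lapply(plans, function(pl) {
    prof <- curvature_profile(pl)
    r_min <- attr(prof, "r_min")
    bad <- prof$s[prof$r < r_hard - eps]
    tibble::tibble(
      label = pl$label, role = pl$role,
      r_min = r_min, s_at_min = attr(prof, "s_at_min"),
      pass = r_min >= r_hard - eps,
      advisory = r_min >= r_hard - eps & r_min < r_comfort - eps,
      span_start = if (length(bad)) min(bad) else NA_real_,
      span_end = if (length(bad)) max(bad) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, r_hard = r_hard, r_comfort = r_comfort,
            class = c("channel_validation", class(out)))
}

#' Check that bundled channels fit the slim applicator base
#'
#' Needle channels bundle inside the uniform base at the vaginal
#' introitus, so two fits are verified: every channel cross-section
#' (bore plus clearance) must lie inside the base disc where it crosses
#' the base, and every pair of centrelines must keep a separation of at
#' least `bore + clearance` along the bundled region.
#'
#' @param plans List of `channel_plan`s; every plan must cross the base
#'   entry plane.
#' @param base A [base_spec()] (or its defaults).
#' @param clearance Minimum wall thickness between channels (mm).
#' @return A list with `ok` (overall flag), `channels` (per-channel
#'   in-disc check) and `pairs` (pairwise minimum centreline distance).
#' @export
bundle_check <- function(plans, base = base_spec(), clearance = 0.4) {
  if (inherits(plans, "channel_plan")) plans <- list(plans)
  stopifnot(length(plans) >= 1)
  axis <- base$axis
  entry_point <- base$anchor - base$length * axis

  in_base <- lapply(plans, function(pl) {
    t_ax <- (pl$samples %*% axis) - sum(entry_point * axis)
    if (max(t_ax) < 0 || min(t_ax) > base$length)
      abort(paste0("channel '", pl$label,
                   "' does not reach the base entry plane"))
    within <- t_ax >= 0 & t_ax <= base$length
    pl$samples[within, , drop = FALSE]
  })

  chan_rows <- purrr::map2_dfr(plans, in_base, function(pl, pts) {
    if (nrow(pts) == 0) {
      return(tibble::tibble(label = pl$label, max_offset = NA_real_,
                            fits_base = TRUE))
    }
    rel <- sweep(pts, 2, base$anchor)
    ax_comp <- rel %*% axis
    radial <- sqrt(pmax(rowSums(rel^2) - ax_comp^2, 0))
    max_off <- max(radial + pl$bore_diameter / 2 + clearance / 2)
    tibble::tibble(label = pl$label, max_offset = max_off,
                   fits_base = max_off <= base$diameter / 2)
  })

  pair_rows <- tibble::tibble(label_a = character(), label_b = character(),
                              min_distance = numeric(), ok = logical())
  if (length(plans) >= 2) {
    combos <- utils::combn(length(plans), 2)
    pair_rows <- purrr::map_dfr(seq_len(ncol(combos)), function(ci) {
      i <- combos[1, ci]; j <- combos[2, ci]
      required <- max(plans[[i]]$bore_diameter, plans[[j]]$bore_diameter) +
        clearance
      dmin <- min_polyline_distance(plans[[i]]$samples, plans[[j]]$samples)
      tibble::tibble(label_a = plans[[i]]$label, label_b = plans[[j]]$label,
                     min_distance = dmin, ok = dmin >= required)
    })
  }
  list(ok = all(chan_rows$fits_base) && all(pair_rows$ok),
       channels = chan_rows, pairs = pair_rows)
}

# Minimum distance between two densely sampled polylines (point-wise;
# samples are at most sample_step apart so the error is below step/2).
min_polyline_distance <- function(a, b) {
  best <- Inf
  block <- 2048L
  for (start in seq(1, nrow(a), by = block)) {
    idx <- start:min(start + block - 1L, nrow(a))
    d2 <- outer(rowSums(a[idx, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * (a[idx, , drop = FALSE] %*% t(b))
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}
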