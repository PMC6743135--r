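#' Calibration template specification
#'
#' The needle-force calibration template: an array of 2.6 mm needle
#' channels with arc radii from 20 to 75 mm in 5 mm steps, each arc
#' bridging a 5 mm wall. Inserting needles through these channels at
#' constant speed and recording axial force yields the radius-constraint
#' data behind the 35 mm hard limit.
#'
#' @param radii Strictly increasing arc radii in mm.
#' @param wall_thickness Wall (plate) thickness bridged by each arc, mm.
#' @param channel_diameter Channel bore in mm.
#' @param spacing Centre-to-centre channel spacing across the plate, mm.
#' @return A `template_spec` object.
#' @export
template_spec <- function(radii = seq(20, 75, by = 5), wall_thickness = 5,
                          channel_diameter = 2.6, spacing = 6) {
  if (any(diff(radii) <= 0) || any(radii <= 0))
    abort("radii must be strictly increasing and positive")
  if (wall_thickness <= 0 || channel_diameter <= 0 || spacing <= 0)
    abort("wall_thickness, channel_diameter and spacing must be > 0")
  structure(list(radii = radii, wall_thickness = wall_thickness,
                 channel_diameter = channel_diameter, spacing = spacing),
            class = "template_spec")
}

#' Generate the curved-channel calibration template
#'
#' Builds a wall plate of the specified thickness and carves one
#' circular-arc channel per radius through it. Each arc lies in its own
#' plane, enters the plate near-normally and exits after bridging the
#' wall; the returned channel plans carry the exact arcs for downstream
#' force simulation.
#'
#' @param spec A [template_spec()].
#' @param pitch Carving voxel pitch in mm (default 0.2).
#' @param arc_margin How far each arc extends beyond the wall on both
#'   sides, mm.
#' @return A `calibration_template`: list with `mesh`, `plans`,
#'   `volume` (carved [label_volume()]), and `report`.
#' @export
make_calibration_template <- function(spec = template_spec(), pitch = 0.2,
                                      arc_margin = 3) {
  stopifnot(inherits(spec, "template_spec"))
  if (spec$spacing <= spec$channel_diameter)
    abort(paste0("channels would overlap: spacing ", spec$spacing,
                 " mm <= channel diameter ", spec$channel_diameter, " mm"))
  wall <- spec$wall_thickness
  margin_y <- 6
  ys <- margin_y + (seq_along(spec$radii) - 1) * spec$spacing

  plans <- purrr::map2(spec$radii, ys, function(r, y) {
    phi_lo <- asin(max(-arc_margin / r, -1))
    phi_hi <- asin(min((wall + arc_margin) / r, 1))
    phi <- seq(phi_lo, phi_hi, by = 0.25 / r)  # ~0.25 mm arc steps
    samples <- cbind(r - r * cos(phi), y, r * sin(phi))
    channel_plan_from_samples(paste0("arc_r", r), "intracavitary", samples,
                              bore_diameter = spec$channel_diameter,
                              tip_diameter = spec$channel_diameter)
  })

  x_in_wall <- max(vapply(spec$radii, function(r)
    r * (1 - cos(asin(min(wall / r, 1)))), numeric(1)))
  block <- mesh_box(c(-4, 0, 0),
                    c(x_in_wall + 5, max(ys) + margin_y, wall))
  vol <- voxelize_mesh(block, pitch)
  rows <- list()
  for (pl in plans) {
    res <- carve_grid(vol, pl, enforce_constraint = FALSE)
    vol <- res$volume
    rows[[length(rows) + 1]] <- tibble::tibble(
      label = pl$label,
      radius = as.numeric(sub("arc_r", "", pl$label)),
      r_min = attr(curvature_profile(pl), "r_min"),
      removed_mm3 = res$removed_mm3)
  }
  mesh <- extract_surface(vol)
  structure(list(mesh = mesh, plans = plans, volume = vol, spec = spec,
                 report = dplyr::bind_rows(rows), pitch = pitch),
            class = "calibration_template")
}

#' @export
print.calibration_template <- function(x, ...) {
  cat("<calibration_template> ", length(x$plans), " channels, radii ",
      min(x$spec$radii), "-", max(x$spec$radii), " mm, wall ",
      x$spec$wall_thickness, " mm, pitch ", x$pitch, " mm\n", sep = "")
  invisible(x)
}
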