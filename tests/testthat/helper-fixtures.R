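# Fixture builders shared across the suite; everything is generated in
# code so tests need no data files.

square_polygon <- function(side = 10, z = 0) {
  rbind(c(0, 0, z), c(side, 0, z), c(side, side, z), c(0, side, z))
}

prism_contours <- function(side = 20, height = 10) {
  contour_set(list(prism = list(square_polygon(side, 0),
                                square_polygon(side, height))))
}

cylinder_contours <- function(radius = 10, height = 30, dz = 2,
                              n_vertices = 180) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  slices <- lapply(seq(0, height, by = dz), function(z) {
    cbind(radius * cos(th), radius * sin(th), z)
  })
  contour_set(list(cyl = slices))
}

# Channel plan on an exact circular arc of the given radius, lying in
# the xz-plane, entering at the origin along +z.
arc_plan <- function(radius, span_deg = 60, step = 0.5, label = NULL,
                     role = "intracavitary", ...) {
  phi <- seq(0, span_deg * pi / 180, by = step / radius)
  samples <- cbind(radius * (1 - cos(phi)), 0, radius * sin(phi))
  channel_plan_from_samples(label %||% paste0("arc", radius), role,
                            samples, ...)
}

straight_plan <- function(from = c(0, 0, -5), to = c(0, 0, 25),
                          role = "intracavitary", label = "straight", ...) {
  fit_spline(waypoint_list(label, rbind(from, to), role = role), ...)
}

slab_mesh <- function(half_xy = 6, depth = 20) {
  mesh_box(c(-half_xy, -half_xy, 0), c(half_xy, half_xy, depth))
}

`%||%` <- rlang::`%||%`
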