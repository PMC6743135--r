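## Voxel-space measurement helpers used by the acceptance checks:
## aperture diameters by circle fit to carved-opening boundaries,
## cross-section diameters, and material run lengths along a ray.

# Algebraic (Kasa) circle fit; returns centre and radius.
fit_circle <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  sol <- unname(qr.solve(A, b))
  cx <- sol[1] / 2; cy <- sol[2] / 2
  r <- sqrt(sol[3] + cx^2 + cy^2)
  list(centre = c(cx, cy), radius = r)
}

layer_index <- function(vol, axis, coord) {
  k <- round((coord - vol$origin[axis]) / vol$spacing[axis]) + 1L
  min(max(k, 1L), dim(vol$grid)[axis])
}

grid_layer <- function(vol, axis, k) {
  switch(axis,
         `1` = vol$grid[k, , ],
         `2` = vol$grid[, k, ],
         `3` = vol$grid[, , k])
}

# In-plane coordinates (mm) of interface midpoints between cells in
# `inside` and 4-neighbour cells in `outside` (both logical matrices).
interface_midpoints <- function(inside, outside, sp, org) {
  pts <- list()
  d <- dim(inside)
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  for (sh in shifts) {
    nb <- matrix(FALSE, d[1], d[2])
    si <- seq_len(d[1]) + sh[1]; sj <- seq_len(d[2]) + sh[2]
    oki <- si >= 1 & si <= d[1]; okj <- sj >= 1 & sj <= d[2]
    nb[oki, okj] <- outside[si[oki], sj[okj]]
    hit <- which(inside & nb, arr.ind = TRUE)
    if (nrow(hit)) {
      pts[[length(pts) + 1]] <- cbind(
        org[1] + (hit[, 1] - 1 + sh[1] / 2) * sp[1],
        org[2] + (hit[, 2] - 1 + sh[2] / 2) * sp[2])
    }
  }
  do.call(rbind, pts)
}

#' Measure a carved channel aperture at a face of the solid
#'
#' Finds the opening (voxels removed by carving) in the outermost
#' occupied layer of the uncarved solid along `axis`, and fits a circle
#' to the boundary between the opening and the remaining material.
#'
#' @param before,after [label_volume()]s of the solid before and after
#'   carving, on the same grid.
#' @param axis Face normal axis (1, 2 or 3).
#' @param side `"max"` (default) for the far face, `"min"` for the near
#'   face.
#' @return Fitted aperture diameter in mm.
#' @export
measure_aperture <- function(before, after, axis = 3,
                             side = c("max", "min")) {
  side <- match.arg(side)
  stopifnot(identical(dim(before$grid), dim(after$grid)))
  occ_k <- which(apply(before$grid, axis, any))
  k <- if (side == "max") max(occ_k) else min(occ_k)
  layer_before <- grid_layer(before, axis, k)
  layer_after <- grid_layer(after, axis, k)
  hole <- layer_before & !layer_after
  if (!any(hole)) abort("no carved opening found in the face layer")
  in_plane <- setdiff(1:3, axis)
  pts <- interface_midpoints(hole, layer_after,
                             before$spacing[in_plane],
                             before$origin[in_plane])
  if (is.null(pts) || nrow(pts) < 3)
    abort("opening boundary too small for a circle fit")
  2 * fit_circle(pts)$radius
}

#' Measure the outer diameter of a cross-section of a solid
#'
#' Slices the volume perpendicular to `axis` at `coord`, fills interior
#' holes (carved channels) of the section footprint, and fits a circle
#' to the outer footprint boundary.
#'
#' @param vol A [label_volume()].
#' @param axis Section normal axis (1, 2 or 3).
#' @param coord Position of the section along `axis` (mm).
#' @return Fitted outer diameter in mm.
#' @export
measure_section_diameter <- function(vol, axis, coord) {
  k <- layer_index(vol, axis, coord)
  layer <- grid_layer(vol, axis, k)
  if (!any(layer)) abort("empty section")
  d <- dim(layer)
  # outside = empty cells connected to the layer border
  empty <- !layer
  lab <- cc_label3d(as.vector(empty), c(d, 1L))$labels
  lab <- matrix(lab, d[1], d[2])
  border_labels <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
  border_labels <- setdiff(border_labels, 0L)
  outside <- matrix(lab %in% border_labels, d[1], d[2])
  footprint <- !outside
  in_plane <- setdiff(1:3, axis)
  pts <- interface_midpoints(footprint, outside,
                             vol$spacing[in_plane], vol$origin[in_plane])
  if (is.null(pts) || nrow(pts) < 3) abort("section boundary too small")
  2 * fit_circle(pts)$radius
}

#' Measure material thickness along an axis-parallel ray
#'
#' Counts the longest contiguous occupied run along the grid column
#' through `(c1, c2)` in the plane perpendicular to `axis`, i.e. the
#' solid-material path length a ray traverses.
#'
#' @param vol A [label_volume()].
#' @param axis Ray direction axis (1, 2 or 3).
#' @param c1,c2 In-plane coordinates of the ray (mm), in axis order with
#'   `axis` removed.
#' @return Material run length in mm.
#' @export
measure_material_run <- function(vol, axis, c1, c2) {
  in_plane <- setdiff(1:3, axis)
  i1 <- layer_index(vol, in_plane[1], c1)
  i2 <- layer_index(vol, in_plane[2], c2)
  column <- switch(axis,
                   `1` = vol$grid[, i1, i2],
                   `2` = vol$grid[i1, , i2],
                   `3` = vol$grid[i1, i2, ])
  if (!any(column)) return(0)
  r <- rle(column)
  max(r$lengths[r$values]) * vol$spacing[axis]
}
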