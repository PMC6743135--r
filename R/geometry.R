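#' Base and design specifications
#'
#' The uniform instrument base is a slim cylinder (12 mm diameter by
#' default) chosen to minimise stress at the vaginal introitus. Its
#' placement relative to the topography is a configuration input: the
#' cylinder spans `anchor - length * axis` to `anchor`.
#'
#' @param diameter Base diameter in mm (default 12).
#' @param length Base length in mm (default 60).
#' @param axis Unit vector from introitus towards the template.
#' @param anchor Centre of the template-side cap (mm).
#' @return A `base_spec` object.
#' @export
base_spec <- function(diameter = 12, length = 60, axis = c(0, 0, 1),
                      anchor = c(0, 0, 0)) {
  if (diameter <= 0 || length <= 0)
    abort("base diameter and length must be > 0")
  axis <- axis / sqrt(sum(axis^2))
  structure(list(diameter = diameter, length = length, axis = axis,
                 anchor = anchor),
            class = "base_spec")
}

#' Build the uniform cylindrical base mesh
#'
#' @param spec A [base_spec()].
#' @param n_segments Circumferential tessellation (default 64, giving a
#'   volume within 0.2% of the analytic cylinder).
#' @return A watertight [surface_mesh()].
#' @export
make_base <- function(spec = base_spec(), n_segments = 64) {
  stopifnot(inherits(spec, "base_spec"))
  mesh <- mesh_cylinder(spec$diameter / 2, spec$length, spec$axis,
                        spec$anchor, n_segments)
  attr(mesh, "base_spec") <- spec
  mesh
}

#' Join the vaginal topography solid to the uniform base
#'
#' Voxel boolean union at the given pitch: both solids are rasterised
#' onto one grid and OR-ed, then the closed surface is re-extracted.
#' The two solids must overlap.
#'
#' @param topography A watertight [surface_mesh()] (or [label_volume()]).
#' @param base A watertight [surface_mesh()] (or [label_volume()]).
#' @param pitch Carving/merging voxel pitch in mm (default 0.2).
#' @return A [surface_mesh()] with the merged [label_volume()] in
#'   attribute `"volume"`.
#' @export
merge_base_and_template <- function(topography, base, pitch = 0.2) {
  vols <- common_grid(list(topography, base), pitch)
  g <- vols[[1]]$grid | vols[[2]]$grid
  if (!any(vols[[1]]$grid & vols[[2]]$grid))
    abort("base does not contact topography (solids are disjoint)")
  merged <- label_volume(g, vols[[1]]$spacing, vols[[1]]$origin)
  out <- extract_surface(merged)
  attr(out, "volume") <- merged
  out
}

# Rasterise several solids (meshes or volumes) onto one common grid.
common_grid <- function(solids, pitch, extra_points = NULL) {
  boxes <- lapply(solids, function(s) {
    if (inherits(s, "label_volume")) {
      list(lo = s$origin - s$spacing / 2,
           hi = s$origin + (dim(s$grid) - 0.5) * s$spacing)
    } else {
      list(lo = apply(s$vertices, 2, min), hi = apply(s$vertices, 2, max))
    }
  })
  lo <- do.call(pmin, lapply(boxes, `[[`, "lo")) - 2 * pitch
  hi <- do.call(pmax, lapply(boxes, `[[`, "hi")) + 2 * pitch
  if (!is.null(extra_points)) {
    lo <- pmin(lo, apply(extra_points, 2, min) - 2 * pitch)
    hi <- pmax(hi, apply(extra_points, 2, max) + 2 * pitch)
  }
  bounds <- list(lo = lo, hi = hi)
  lapply(solids, function(s) {
    if (inherits(s, "label_volume")) resample_volume(s, pitch, bounds)
    else voxelize_mesh(s, pitch, bounds)
  })
}

# Nearest-neighbour resampling of a label volume onto a new grid.
resample_volume <- function(vol, pitch, bounds) {
  n <- pmax(ceiling((bounds$hi - bounds$lo) / pitch) + 1L, 3L)
  origin <- bounds$lo + pitch / 2
  ax_idx <- lapply(1:3, function(a) {
    centres <- origin[a] + (seq_len(n[a]) - 1) * pitch
    idx <- round((centres - vol$origin[a]) / vol$spacing[a]) + 1L
    ifelse(idx >= 1L & idx <= dim(vol$grid)[a], idx, NA_integer_)
  })
  g <- array(FALSE, n)
  ok <- lapply(ax_idx, function(ix) which(!is.na(ix)))
  sub <- vol$grid[ax_idx[[1]][ok[[1]]], ax_idx[[2]][ok[[2]]],
                  ax_idx[[3]][ok[[3]]], drop = FALSE]
  g[ok[[1]], ok[[2]], ok[[3]]] <- sub
  label_volume(g, rep(pitch, 3), origin)
}

#' Carve a swept needle channel out of a solid
#'
#' Voxel boolean subtraction of the swept tube: a sphere of the local
#' channel diameter is swept along the channel centreline. The local
#' diameter equals the bore everywhere except over the final
#' `taper_length` of an interstitial channel before its surface exit
#' point, where it tapers linearly to the tip diameter. Channels are
#' re-validated against the hard radius limit before carving.
#'
#' @param solid A [surface_mesh()] or [label_volume()].
#' @param plan A `channel_plan`.
#' @param pitch Voxel pitch in mm (default 0.2); must be at most
#'   `tip_diameter / 4`.
#' @param r_hard Hard radius limit used for re-validation (mm).
#' @param enforce_constraint Set `FALSE` to carve a deliberately
#'   sub-limit channel (calibration templates).
#' @return A [surface_mesh()] with attributes `"volume"` (carved
#'   [label_volume()]) and `"removed_mm3"`.
#' @export
carve_channel <- function(solid, plan, pitch = 0.2, r_hard = 35,
                          enforce_constraint = TRUE) {
  vol <- if (inherits(solid, "label_volume")) {
    if (!isTRUE(all.equal(max(solid$spacing), min(solid$spacing))))
      abort("carving requires an isotropic grid")
    solid
  } else {
    voxelize_mesh(solid, pitch,
                  bounds = list(lo = apply(solid$vertices, 2, min) - 2 * pitch,
                                hi = apply(solid$vertices, 2, max) + 2 * pitch))
  }
  res <- carve_grid(vol, plan, r_hard = r_hard,
                    enforce_constraint = enforce_constraint)
  out <- extract_surface(res$volume)
  attr(out, "volume") <- res$volume
  attr(out, "removed_mm3") <- res$removed_mm3
  out
}

carve_grid <- function(vol, plan, r_hard = 35, enforce_constraint = TRUE,
                       record_tube = FALSE) {
  stopifnot(inherits(plan, "channel_plan"))
  pitch <- vol$spacing[1]
  if (pitch > plan$tip_diameter / 4)
    abort(paste0("voxel pitch ", pitch, " mm too coarse for tip diameter ",
                 plan$tip_diameter, " mm (needs <= tip/4)"))
  if (enforce_constraint) {
    r_min <- attr(curvature_profile(plan), "r_min")
    if (r_min < r_hard - 1e-6)
      abort(paste0("channel '", plan$label, "' violates the hard radius ",
                   "limit (r_min = ", format(r_min, digits = 5), " mm < ",
                   r_hard, " mm); not carving an unvalidated plan"))
  }
  # densify the centreline to one sample per voxel pitch
  pts <- plan$samples
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  s_dense <- seq(0, arc[length(arc)], by = max(pitch / 2, 0.05))
  dense <- sapply(1:3, function(j) approx(arc, pts[, j], xout = s_dense,
                                          ties = "ordered")$y)

  radius_at <- channel_radius_profile(vol, plan, dense, s_dense)

  g <- vol$grid
  d <- dim(g)
  removed <- 0
  tube <- if (record_tube) array(FALSE, d) else NULL
  for (i in seq_along(s_dense)) {
    p <- dense[i, ]
    r <- radius_at[i]
    sel <- sphere_voxels(p, r, vol$origin, pitch, d)
    if (length(sel) == 0) next
    removed <- removed + sum(g[sel])
    g[sel] <- FALSE
    if (record_tube) tube[sel] <- TRUE
  }
  list(volume = label_volume(g, vol$spacing, vol$origin),
       removed_mm3 = removed * pitch^3,
       tube = if (record_tube) label_volume(tube, vol$spacing, vol$origin))
}

# Local channel radius along the densified centreline, applying the
# linear tip taper over the final taper_length before the point where
# the centreline last leaves the solid.
channel_radius_profile <- function(vol, plan, dense, s_dense) {
  r_bore <- plan$bore_diameter / 2
  if (plan$tip_diameter >= plan$bore_diameter || plan$role == "loop")
    return(rep(r_bore, length(s_dense)))
  idx <- sweep(dense, 2, vol$origin)
  idx <- round(sweep(idx, 2, vol$spacing, "/")) + 1
  d <- dim(vol$grid)
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  occ <- rep(FALSE, nrow(dense))
  if (any(inside)) {
    lin <- idx[inside, 1] + (idx[inside, 2] - 1) * d[1] +
      (idx[inside, 3] - 1) * as.numeric(d[1]) * d[2]
    occ[inside] <- vol$grid[lin]
  }
  if (!any(occ)) return(rep(r_bore, length(s_dense)))
  s_exit <- s_dense[max(which(occ))]
  dia <- plan$bore_diameter +
    (plan$tip_diameter - plan$bore_diameter) *
    pmin(pmax((s_dense - (s_exit - plan$taper_length)) /
                plan$taper_length, 0), 1)
  dia / 2
}

sphere_voxels <- function(p, r, origin, pitch, d) {
  rng <- lapply(1:3, function(a) {
    lo <- max(ceiling((p[a] - r - origin[a]) / pitch + 1 - 1e-9), 1)
    hi <- min(floor((p[a] + r - origin[a]) / pitch + 1 + 1e-9), d[a])
    if (hi < lo) return(NULL)
    lo:hi
  })
  if (any(vapply(rng, is.null, logical(1)))) return(integer(0))
  dx2 <- (origin[1] + (rng[[1]] - 1) * pitch - p[1])^2
  dy2 <- (origin[2] + (rng[[2]] - 1) * pitch - p[2])^2
  dz2 <- (origin[3] + (rng[[3]] - 1) * pitch - p[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  keep <- d2 <= r^2
  if (!any(keep)) return(integer(0))
  lin <- outer(outer(rng[[1]], (rng[[2]] - 1) * d[1], "+"),
               (rng[[3]] - 1) * as.numeric(d[1]) * d[2], "+")
  lin[keep]
}

#' Interlink two channels into a fillable reconstruction loop
#'
#' Joins channel `a`, a bridge spline through the supplied waypoints,
#' and channel `b` reversed into one continuous loop plan. Filled with
#' water or aqueous gel, the loop provides MRI-visible anchor points for
#' applicator reconstruction during dose planning. Curvature validation
#' applies to the joined plan; a bridge violating the hard limit is
#' reported with a warning, never silently accepted.
#'
#' @param plan_a,plan_b `channel_plan`s whose tips the bridge connects.
#' @param bridge_waypoints Matrix of intermediate bridge waypoints (mm).
#' @param label Label for the joined plan.
#' @param r_hard Hard radius limit (mm) used for the warning.
#' @return A `channel_plan` with role `"loop"`.
#' @export
make_loop_channel <- function(plan_a, plan_b, bridge_waypoints,
                              label = paste0(plan_a$label, "+", plan_b$label),
                              r_hard = 35) {
  stopifnot(inherits(plan_a, "channel_plan"),
            inherits(plan_b, "channel_plan"))
  end_a <- plan_a$samples[nrow(plan_a$samples), ]
  end_b <- plan_b$samples[nrow(plan_b$samples), ]
  bridge_wp <- waypoint_list(paste0(label, "_bridge"),
                             rbind(end_a, as.matrix(bridge_waypoints), end_b),
                             role = "loop")
  step <- min(plan_a$sample_step, plan_b$sample_step)
  bridge <- fit_spline(bridge_wp, sample_step = step,
                       bore_diameter = plan_a$bore_diameter,
                       tip_diameter = plan_a$bore_diameter)
  samples <- rbind(plan_a$samples,
                   bridge$samples[-1, , drop = FALSE],
                   plan_b$samples[rev(seq_len(nrow(plan_b$samples) - 1)), ,
                                  drop = FALSE])
  joined <- channel_plan_from_samples(label, "loop", samples,
                                      bore_diameter = plan_a$bore_diameter)
  r_min <- attr(curvature_profile(joined), "r_min")
  if (r_min < r_hard)
    warn(paste0("loop '", label, "' violates the hard radius limit: r_min = ",
                format(r_min, digits = 5), " mm < ", r_hard, " mm"))
  joined
}

#' Assemble and carve a full applicator design
#'
#' @param topography Watertight topography [surface_mesh()] (from
#'   [extract_surface()]/[smooth_surface()]).
#' @param base A [base_spec()].
#' @param channels List of `channel_plan`s.
#' @param loop_pairs Optional list of `list(a =, b =, bridge =)` entries
#'   naming two channel labels to interlink with the given bridge
#'   waypoints; each pair is replaced by its joined loop before carving.
#' @param pitch Carving voxel pitch in mm (default 0.2).
#' @return An `applicator_design` object.
#' @export
applicator_design <- function(topography, base = base_spec(),
                              channels = list(), loop_pairs = list(),
                              pitch = 0.2) {
  stopifnot(inherits(topography, "surface_mesh"),
            inherits(base, "base_spec"))
  structure(list(topography = topography, base = base,
                 channels = channels, loop_pairs = loop_pairs,
                 pitch = pitch),
            class = "applicator_design")
}

#' @describeIn applicator_design Validate, merge, and carve the design
#'   into the printable applicator solid.
#' @param design An `applicator_design`.
#' @param r_hard,r_comfort Radius limits passed to [validate_channels()].
#' @param clearance Bundle clearance in mm.
#' @export
build_applicator <- function(design, r_hard = 35, r_comfort = 50,
                             clearance = 0.4) {
  stopifnot(inherits(design, "applicator_design"))
  channels <- design$channels
  names(channels) <- vapply(channels, `[[`, character(1), "label")

  for (lp in design$loop_pairs) {
    if (!all(c(lp$a, lp$b) %in% names(channels)))
      abort(paste0("loop pair references unknown channel(s): ",
                   lp$a, ", ", lp$b))
    joined <- make_loop_channel(channels[[lp$a]], channels[[lp$b]],
                                lp$bridge, r_hard = r_hard)
    channels[[lp$a]] <- NULL
    channels[[lp$b]] <- NULL
    channels[[joined$label]] <- joined
  }
  if (length(channels) == 0 && length(design$channels) > 0)
    abort("no channels left after loop joining")

  if (length(channels) > 0) {
    report <- validate_channels(channels, r_hard, r_comfort)
    if (!all(report$pass)) {
      bad <- report$label[!report$pass]
      abort(paste0("channel validation failed for: ",
                   paste(bad, collapse = ", "), "; aborting before carving"))
    }
    bc <- bundle_check(channels, design$base, clearance)
    if (!bc$ok)
      abort("bundle check failed: channels do not fit the base")
  } else {
    report <- NULL
  }

  base_mesh <- make_base(design$base)
  all_samples <- if (length(channels))
    do.call(rbind, lapply(channels, `[[`, "samples")) else NULL
  vols <- common_grid(list(design$topography, base_mesh), design$pitch,
                      extra_points = all_samples)
  if (!any(vols[[1]]$grid & vols[[2]]$grid))
    abort("base does not contact topography (solids are disjoint)")
  solid0 <- label_volume(vols[[1]]$grid | vols[[2]]$grid,
                         vols[[1]]$spacing, vols[[1]]$origin)

  vol <- solid0
  rows <- list()
  for (ch in channels) {
    res <- carve_grid(vol, ch, r_hard = r_hard, record_tube = TRUE)
    vol <- res$volume
    outside_tube <- res$tube$grid & !solid0$grid
    n_open <- if (any(outside_tube))
      cc_label3d(as.vector(outside_tube), dim(outside_tube))$n_components
    else 0L
    rows[[length(rows) + 1]] <- tibble::tibble(
      label = ch$label, role = ch$role,
      r_min = attr(curvature_profile(ch), "r_min"),
      removed_mm3 = res$removed_mm3,
      openings = n_open)
  }
  mesh <- extract_surface(vol)
  m <- mesh_metrics(mesh)
  structure(
    list(mesh = mesh, volume = vol,
         report = dplyr::bind_rows(rows),
         validation = report,
         metrics = m,
         solid_volume_mm3 = volume_of(vol),
         pitch = design$pitch),
    class = "applicator_build")
}

#' @export
print.applicator_build <- function(x, ...) {
  cat("<applicator_build> pitch ", x$pitch, " mm, volume ",
      format(x$solid_volume_mm3, digits = 7), " mm^3, watertight: ",
      x$metrics$watertight, "\n", sep = "")
  if (!is.null(x$report) && nrow(x$report)) print(x$report)
  invisible(x)
}
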