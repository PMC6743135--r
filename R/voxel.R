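#' Binary label volumes
#'
#' The working representation between contours and meshes: a 3D logical
#' occupancy array with isotropic-or-not spacing (mm) and the position of
#' the centre of voxel `[1, 1, 1]`.
#'
#' @param grid Logical 3D array.
#' @param spacing Numeric length-3 voxel spacing (mm), strictly positive.
#' @param origin Numeric length-3 centre of the first voxel (mm).
#' @return A `label_volume` object.
#' @export
label_volume <- function(grid, spacing, origin) {
  spacing <- rep_len(as.numeric(spacing), 3)
  origin <- rep_len(as.numeric(origin), 3)
  stopifnot(is.logical(grid), length(dim(grid)) == 3, all(spacing > 0))
  structure(list(grid = grid, spacing = spacing, origin = origin),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat("<label_volume> ", paste(d, collapse = " x "), " voxels, spacing ",
      paste(format(x$spacing), collapse = "/"), " mm, ",
      sum(x$grid), " occupied (", format(volume_of(x), digits = 6),
      " mm^3)\n", sep = "")
  invisible(x)
}

#' Occupied volume of a label volume
#'
#' @param vol A [label_volume()].
#' @return Occupied volume in mm^3.
#' @export
volume_of <- function(vol) sum(vol$grid) * prod(vol$spacing)

# Voxel-centre coordinates along one axis.
axis_centres <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$grid)[axis]) - 1) * vol$spacing[axis]
}

#' Rasterise a contoured structure into a binary labelmap
#'
#' Converts the stacked planar contours of one structure into voxel
#' occupancy: a voxel centre is occupied iff it lies inside the structure.
#' Occupancy between slices is decided by point-in-polygon membership
#' against the nearest slice's contour (nearest-slice extrusion); the
#' solid spans from the first to the last slice position. A one-voxel
#' empty padding is guaranteed on all sides.
#'
#' Contour planes must be perpendicular to a coordinate axis.
#'
#' @param contours A [contour_set()].
#' @param structure_label Name of the structure to rasterise.
#' @param spacing Isotropic voxel spacing in mm (default 0.5); must be at
#'   most half the smallest inter-slice distance.
#' @return A [label_volume()].
#' @export
voxelize <- function(contours, structure_label, spacing = 0.5) {
  stopifnot(inherits(contours, "contour_set"))
  if (!structure_label %in% names(contours$structures))
    abort(paste0("no structure named '", structure_label, "'"))
  slices <- contours$structures[[structure_label]]
  if (length(slices) == 0) abort("empty structure")
  if (length(slices) < 2)
    abort("cannot concatenate one slice: structure needs >= 2 slices")
  normal <- contours$slice_normal
  ax <- which(abs(abs(normal) - 1) < 1e-9)
  if (length(ax) != 1)
    abort("slice normal must be along a coordinate axis for rasterisation")
  in_plane <- setdiff(1:3, ax)

  pos <- vapply(slices, function(p) mean(p[, ax]), numeric(1))
  gaps <- diff(sort(pos))
  if (any(gaps <= 0)) abort("slices must have distinct positions")
  if (spacing > min(gaps) / 2 + 1e-12)
    abort(paste0("spacing too coarse: ", spacing,
                 " mm exceeds half the inter-slice distance (",
                 format(min(gaps) / 2), " mm)"))

  all_pts <- do.call(rbind, slices)
  lo <- apply(all_pts, 2, min) - spacing
  hi <- apply(all_pts, 2, max) + spacing
  n <- pmax(ceiling((hi - lo) / spacing) + 1L, 3L)
  origin <- lo
  grid <- array(FALSE, dim = n)

  cx <- origin[in_plane[1]] + (seq_len(n[in_plane[1]]) - 1) * spacing
  cy <- origin[in_plane[2]] + (seq_len(n[in_plane[2]]) - 1) * spacing
  pts <- cbind(rep(cx, times = length(cy)), rep(cy, each = length(cx)))

  # half-open axial coverage [first, last): the grid is anchored at the
  # first slice, so a prism of height h covers exactly h / spacing layers
  ck <- origin[ax] + (seq_len(n[ax]) - 1) * spacing
  inside_span <- ck >= min(pos) - 1e-12 & ck < max(pos) - 1e-12
  nearest <- vapply(ck, function(z) which.min(abs(pos - z)), integer(1))

  masks <- vector("list", length(slices))
  idx <- array(seq_len(prod(n)), dim = n)
  for (k in which(inside_span)) {
    s <- nearest[k]
    if (is.null(masks[[s]])) {
      poly <- slices[[s]][, in_plane, drop = FALSE]
      masks[[s]] <- points_in_polygon(pts, poly)
    }
    layer <- matrix(masks[[s]], nrow = length(cx))
    sel <- switch(ax,
                  `1` = idx[k, , ],
                  `2` = idx[, k, ],
                  `3` = idx[, , k])
    grid[as.vector(sel)] <- as.vector(layer)
  }
  if (!any(grid)) abort("rasterisation produced no occupied voxels")
  label_volume(grid, rep(spacing, 3), origin)
}

# Even-odd rule point-in-polygon, vectorised over points.
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- rep(FALSE, length(px))
  bb <- c(range(poly[, 1]), range(poly[, 2]))
  in_bb <- px >= bb[1] & px <= bb[2] & py >= bb[3] & py <= bb[4]
  if (!any(in_bb)) return(inside)
  qx <- px[in_bb]; qy <- py[in_bb]
  hit <- rep(FALSE, length(qx))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    xi <- poly[i, 1]; xj <- poly[j, 1]
    crosses <- (yi > qy) != (yj > qy)
    if (any(crosses)) {
      xint <- xi + (qy[crosses] - yi) / (yj - yi) * (xj - xi)
      flip <- qx[crosses] < xint
      hit[crosses] <- xor(hit[crosses], flip)
    }
    j <- i
  }
  inside[in_bb] <- hit
  inside
}

#' Rasterise a closed surface mesh into a binary labelmap
#'
#' Parity-count voxelisation: a voxel centre is occupied iff a ray along
#' +z from below crosses the mesh an odd number of times before reaching
#' it. Rasterisation uses a top-left fill rule plus a sub-voxel sample
#' offset so that axis-aligned faces are handled deterministically.
#'
#' @param mesh A watertight [surface_mesh()].
#' @param pitch Voxel pitch in mm.
#' @param bounds Optional list with `lo` and `hi` corners (mm) fixing the
#'   grid extent (used to place several solids on one grid); defaults to
#'   the mesh bounding box padded by two voxels.
#' @return A [label_volume()].
#' @export
voxelize_mesh <- function(mesh, pitch = 0.2, bounds = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$faces) == 0) abort("cannot voxelize an empty mesh")
  v <- mesh$vertices
  if (is.null(bounds)) {
    bounds <- list(lo = apply(v, 2, min) - 2 * pitch,
                   hi = apply(v, 2, max) + 2 * pitch)
  }
  lo <- bounds$lo; hi <- bounds$hi
  n <- pmax(ceiling((hi - lo) / pitch) + 1L, 3L)
  origin <- lo + pitch / 2  # centres offset from the bound corner
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  cx <- origin[1] + (seq_len(nx) - 1) * pitch + 1.37e-7 * pitch
  cy <- origin[2] + (seq_len(ny) - 1) * pitch + 2.41e-7 * pitch

  f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  # signed area in the xy projection; skip ray-parallel triangles
  area2 <- (B[, 1] - A[, 1]) * (C[, 2] - A[, 2]) -
    (B[, 2] - A[, 2]) * (C[, 1] - A[, 1])
  keep <- abs(area2) > 1e-12
  col_id <- vector("list", sum(keep))
  z_hit <- vector("list", sum(keep))
  out_i <- 0L
  for (t in which(keep)) {
    a <- A[t, ]; b <- B[t, ]; c_ <- C[t, ]
    if (area2[t] < 0) { tmp <- b; b <- c_; c_ <- tmp }  # force CCW in xy
    xr <- range(a[1], b[1], c_[1]); yr <- range(a[2], b[2], c_[2])
    ix <- which(cx >= xr[1] - pitch & cx <= xr[2] + pitch)
    iy <- which(cy >= yr[1] - pitch & cy <= yr[2] + pitch)
    if (length(ix) == 0 || length(iy) == 0) next
    px <- rep(cx[ix], times = length(iy))
    py <- rep(cy[iy], each = length(ix))
    e1 <- edge_test(a, b, px, py)
    e2 <- edge_test(b, c_, px, py)
    e3 <- edge_test(c_, a, px, py)
    inside <- e1 & e2 & e3
    if (!any(inside)) next
    px <- px[inside]; py <- py[inside]
    # plane z at (px, py)
    nrm <- c((b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
             (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
             (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1]))
    zc <- a[3] - (nrm[1] * (px - a[1]) + nrm[2] * (py - a[2])) / nrm[3]
    cols <- rep(ix, times = length(iy))[inside] +
      (rep(iy, each = length(ix))[inside] - 1) * nx
    out_i <- out_i + 1L
    col_id[[out_i]] <- cols
    z_hit[[out_i]] <- zc
  }
  grid <- array(FALSE, dim = n)
  if (out_i > 0) {
    cols <- unlist(col_id[seq_len(out_i)])
    zs <- unlist(z_hit[seq_len(out_i)])
    o <- order(cols, zs)
    cols <- cols[o]; zs <- zs[o]
    runs <- rle(cols)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    odd <- runs$lengths %% 2L == 1L
    if (any(odd)) {
      warn(paste0(sum(odd), " voxel column(s) with odd crossing parity; ",
                  "dropping the last crossing in each"))
      ends[odd] <- ends[odd] - 1L
    }
    oz <- origin[3]
    # enter/exit pairs: odd positions within each column run are entries
    run_of <- rep(seq_along(starts), runs$lengths)
    within <- sequence(runs$lengths)
    live <- within <= (ends - starts + 1L)[run_of]
    zlive <- zs[live]; rlive <- run_of[live]; wlive <- within[live]
    is_enter <- wlive %% 2L == 1L
    z1 <- zlive[is_enter]; z2 <- zlive[!is_enter]
    colv <- runs$values[rlive[is_enter]]
    k1 <- pmax(ceiling((z1 - oz) / pitch + 1 - 1e-9), 1)
    k2 <- pmin(floor((z2 - oz) / pitch + 1 + 1e-9), nz)
    lens <- k2 - k1 + 1
    ok <- lens > 0
    if (any(ok)) {
      lens <- as.integer(lens[ok])
      ks <- sequence(lens) - 1L + rep(as.integer(k1[ok]), lens)
      lin <- rep(colv[ok], lens) + (ks - 1) * as.numeric(nx * ny)
      grid[lin] <- TRUE
    }
  }
  label_volume(grid, rep(pitch, 3), origin)
}

# Top-left rule edge test for a CCW edge a -> b: interior is E >= 0, with
# E == 0 kept only on top or left edges so shared edges are not counted
# twice.
edge_test <- function(a, b, px, py) {
  e <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
  dy <- b[2] - a[2]; dx <- b[1] - a[1]
  top_left <- dy > 0 || (dy == 0 && dx < 0)
  if (top_left) e >= 0 else e > 0
}
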