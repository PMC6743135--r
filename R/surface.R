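#' Smoothing specification
#'
#' A single smoothing factor in `[0, 1]` (default 0.5) controlling the
#' shrink-resistant Taubin smoothing applied to reconstructed surfaces.
#' The factor maps to `round(20 * factor)` Taubin iterations with
#' lambda = 0.5 and mu = -0.53; factor 0 is the identity.
#'
#' @param factor Real in `[0, 1]`.
#' @return A `smoothing_spec` object.
#' @export
smoothing_spec <- function(factor = 0.5) {
  if (!is.numeric(factor) || length(factor) != 1 ||
      factor < 0 || factor > 1)
    abort("smoothing factor must be a single number in [0, 1]")
  structure(list(factor = factor, lambda = 0.5, mu = -0.53,
                 iterations = round(20 * factor)),
            class = "smoothing_spec")
}

#' Extract the closed isosurface of a binary labelmap
#'
#' Builds the watertight triangle mesh of the 0.5-occupancy isosurface:
#' the boundary faces between occupied and empty voxels, with
#' checkerboard voxel configurations (two solids meeting only along an
#' edge) resolved by filling so that every edge of the output is shared
#' by exactly two faces. If the occupancy splits into several connected
#' components, the largest is kept with a warning.
#'
#' @param volume A [label_volume()] with at least one occupied voxel.
#' @return A [surface_mesh()] in mm.
#' @export
extract_surface <- function(volume) {
  stopifnot(inherits(volume, "label_volume"))
  g <- volume$grid
  if (!any(g)) abort("volume has no occupied voxels")
  # defensive padding so boundary faces always exist
  d <- dim(g)
  gp <- array(FALSE, d + 2L)
  gp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- g
  origin <- volume$origin - volume$spacing

  gp <- fix_checkerboard(gp)

  cc <- cc_label3d(as.vector(gp), dim(gp))
  if (cc$n_components > 1) {
    warn(paste0("occupancy has ", cc$n_components,
                " connected components; keeping the largest (",
                cc$sizes[1], " voxels)"))
    gp <- array(cc$labels == 1L, dim(gp))
  }
  voxel_boundary_mesh(gp, volume$spacing, origin)
}

# Fill one voxel of every 2x2 in-plane checkerboard pattern; such
# patterns are the only source of non-manifold (4-face) edges in the
# voxel boundary surface.
fix_checkerboard <- function(g) {
  repeat {
    changed <- FALSE
    d <- dim(g)
    for (perm in list(c(1, 2, 3), c(1, 3, 2), c(2, 3, 1))) {
      h <- aperm(g, perm)
      dh <- dim(h)
      a <- h[-dh[1], -dh[2], , drop = FALSE]  # (i,   j)
      b <- h[-1,     -dh[2], , drop = FALSE]  # (i+1, j)
      cc <- h[-dh[1], -1,    , drop = FALSE]  # (i,   j+1)
      dd <- h[-1,     -1,    , drop = FALSE]  # (i+1, j+1)
      diag1 <- a & dd & !b & !cc  # fill (i+1, j)
      diag2 <- b & cc & !a & !dd  # fill (i, j)
      if (any(diag1) || any(diag2)) {
        changed <- TRUE
        hb <- h[-1, -dh[2], , drop = FALSE] | diag1
        h[-1, -dh[2], ] <- hb
        ha <- h[-dh[1], -dh[2], , drop = FALSE] | diag2
        h[-dh[1], -dh[2], ] <- ha
        g <- aperm(h, order(perm))
      }
    }
    if (!changed) return(g)
  }
}

voxel_boundary_mesh <- function(g, spacing, origin) {
  d <- dim(g)
  nxc <- d[1] + 1L; nyc <- d[2] + 1L  # corner grid dims
  corner_key <- function(ci, cj, ck) {
    ci + cj * as.numeric(nxc) + ck * as.numeric(nxc) * nyc
  }
  shift_empty <- function(axis, dir) {
    # TRUE where the neighbour voxel in (axis, dir) is empty or outside;
    # the grid is padded, so occupied voxels never touch the border.
    nb <- array(FALSE, d)
    src <- lapply(d, seq_len)
    dst <- lapply(d, seq_len)
    if (dir == 1L) {
      src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1L)
    } else {
      src[[axis]] <- 1:(d[axis] - 1L); dst[[axis]] <- 2:d[axis]
    }
    nb <- do.call(`[<-`, c(list(nb), dst,
                           list(value = do.call(`[`, c(list(g), src)))))
    !nb
  }
  tris <- vector("list", 6)
  ti <- 0L
  for (axis in 1:3) {
    for (dir in c(1L, -1L)) {
      face_here <- g & shift_empty(axis, dir)
      w <- which(face_here, arr.ind = TRUE)
      if (nrow(w) == 0) next
      i <- w[, 1]; j <- w[, 2]; k <- w[, 3]
      # corner coordinates (0-based): voxel v spans corners v-1 .. v
      q <- quad_corners(axis, dir, i, j, k)
      key <- lapply(q, function(cn) corner_key(cn[, 1], cn[, 2], cn[, 3]))
      ti <- ti + 1L
      tris[[ti]] <- rbind(
        cbind(key[[1]], key[[2]], key[[3]]),
        cbind(key[[1]], key[[3]], key[[4]])
      )
    }
  }
  tri_keys <- do.call(rbind, tris[seq_len(ti)])
  ukeys <- unique(as.vector(tri_keys))
  faces <- matrix(match(tri_keys, ukeys), ncol = 3)
  ck <- ukeys
  ci <- ck %% nxc
  cj <- (ck %/% nxc) %% nyc
  cz <- ck %/% (as.numeric(nxc) * nyc)
  vertices <- cbind(origin[1] + (ci - 0.5) * spacing[1],
                    origin[2] + (cj - 0.5) * spacing[2],
                    origin[3] + (cz - 0.5) * spacing[3])
  surface_mesh(vertices, faces)
}

# Corner cycles (counter-clockwise seen from outside) for each face type.
quad_corners <- function(axis, dir, i, j, k) {
  ii <- i - 1L; jj <- j - 1L; kk <- k - 1L  # low corner (0-based)
  if (axis == 1 && dir == 1) {        # +x
    list(cbind(i, jj, kk), cbind(i, j, kk), cbind(i, j, k), cbind(i, jj, k))
  } else if (axis == 1) {             # -x
    list(cbind(ii, jj, kk), cbind(ii, jj, k), cbind(ii, j, k), cbind(ii, j, kk))
  } else if (axis == 2 && dir == 1) { # +y
    list(cbind(ii, j, kk), cbind(ii, j, k), cbind(i, j, k), cbind(i, j, kk))
  } else if (axis == 2) {             # -y
    list(cbind(ii, jj, kk), cbind(i, jj, kk), cbind(i, jj, k), cbind(ii, jj, k))
  } else if (axis == 3 && dir == 1) { # +z
    list(cbind(ii, jj, k), cbind(i, jj, k), cbind(i, j, k), cbind(ii, j, k))
  } else {                            # -z
    list(cbind(ii, jj, kk), cbind(ii, j, kk), cbind(i, j, kk), cbind(i, jj, kk))
  }
}

#' Taubin-smooth a watertight surface
#'
#' Shrink-resistant two-step Laplacian smoothing: each iteration moves
#' vertices by `lambda` toward the neighbour average and then by `mu`
#' (negative, slightly larger in magnitude) away from it, which smooths
#' without the volume loss of plain Laplacian smoothing. The mesh
#' topology is untouched, so watertightness, orientation, component
#' count and Euler characteristic are preserved.
#'
#' @param mesh A watertight [surface_mesh()].
#' @param spec A [smoothing_spec()] (or a bare factor in `[0, 1]`).
#' @return The smoothed [surface_mesh()].
#' @export
smooth_surface <- function(mesh, spec = smoothing_spec(0.5)) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.numeric(spec)) spec <- smoothing_spec(spec)
  if (!mesh_is_watertight(mesh))
    abort("smooth_surface requires a watertight mesh")
  if (spec$iterations == 0) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  adj <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                              dims = c(nrow(v), nrow(v)),
                              use.last.ij = TRUE)
  deg <- Matrix::rowSums(adj)
  deg[deg == 0] <- 1
  W <- adj / deg
  for (it in seq_len(spec$iterations)) {
    v <- v + spec$lambda * (as.matrix(W %*% v) - v)
    v <- v + spec$mu * (as.matrix(W %*% v) - v)
  }
  surface_mesh(v, f)
}
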