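#' Triangle surface meshes
#'
#' The applicator solid representation: vertex coordinates in mm and
#' 1-based vertex-index triples. Watertightness is always computed from
#' the connectivity, never assumed.
#'
#' @param vertices n x 3 numeric matrix of vertex positions (mm).
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) abort("vertices must be n x 3")
  if (ncol(faces) != 3) abort("faces must be m x 3")
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    abort("face indices out of range")
  structure(list(vertices = vertices, faces = faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  m <- mesh_metrics(x)
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  cat(sprintf("  volume %.3f mm^3, area %.3f mm^2, watertight: %s, components: %d\n",
              m$volume_mm3, m$area_mm2, m$watertight, m$n_components))
  invisible(x)
}

# Undirected edge keys as doubles (safe below 2^26 vertices).
mesh_edge_keys <- function(faces, n_vertices) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  (lo - 1) * as.numeric(n_vertices) + hi
}

mesh_is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  keys <- sort(mesh_edge_keys(mesh$faces, nrow(mesh$vertices)))
  r <- rle(keys)
  all(r$lengths == 2)
}

# Connected components over shared vertices (mesh-level, not voxel-level).
mesh_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  if (nv == 0) return(integer(0))
  f <- mesh$faces
  parent <- seq_len(nv)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(f))) {
    a <- find(f[r, 1]); b <- find(f[r, 2]); c <- find(f[r, 3])
    parent[b] <- a
    parent[find(c)] <- a
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  match(roots, unique(roots))
}

#' Mesh quality metrics
#'
#' Signed volume by the divergence theorem, total surface area, a
#' watertight flag (every edge shared by exactly two faces), and the
#' number of connected components (vertices shared between faces).
#'
#' @param mesh A [surface_mesh()].
#' @return A list with `volume_mm3`, `area_mm2`, `watertight`,
#'   `n_components`, and `euler_characteristic`.
#' @export
mesh_metrics <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0)
    return(list(volume_mm3 = 0, area_mm2 = 0, watertight = FALSE,
                n_components = 0L, euler_characteristic = NA_integer_))
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cross3(b - a, c_ - a)
  vol <- sum(rowSums(a * cr)) / 6
  area <- sum(sqrt(rowSums(cr^2))) / 2
  used <- unique(as.vector(f))
  n_edges <- length(unique(mesh_edge_keys(f, nrow(v))))
  comps <- mesh_components(mesh)
  list(volume_mm3 = vol, area_mm2 = area,
       watertight = mesh_is_watertight(mesh),
       n_components = length(unique(comps[used])),
       euler_characteristic = length(used) - n_edges + nrow(f))
}

cross3 <- function(u, w) {
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

# Merge vertices closer than tol (exact duplicates after rounding).
merge_mesh_vertices <- function(vertices, faces, tol = 1e-5) {
  key <- apply(round(vertices / tol) * tol, 1, paste, collapse = "/")
  first <- !duplicated(key)
  map <- match(key, key[first])
  new_v <- vertices[first, , drop = FALSE]
  new_f <- matrix(map[faces], ncol = 3)
  # drop degenerate faces produced by merging
  ok <- new_f[, 1] != new_f[, 2] & new_f[, 2] != new_f[, 3] &
    new_f[, 1] != new_f[, 3]
  surface_mesh(new_v, new_f[ok, , drop = FALSE])
}

#' Primitive meshes
#'
#' Watertight primitives used for bases, fixtures and tests: an
#' axis-aligned box, a tessellated cylinder, and an icosphere obtained by
#' subdividing an icosahedron.
#'
#' @param lo,hi Opposite box corners (mm).
#' @return A [surface_mesh()].
#' @export
mesh_box <- function(lo, hi) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order: (x fastest), faces with outward normals
  f <- rbind(
    c(1, 7, 3), c(1, 5, 7),  # x = lo
    c(2, 4, 8), c(2, 8, 6),  # x = hi
    c(1, 2, 6), c(1, 6, 5),  # y = lo
    c(3, 7, 8), c(3, 8, 4),  # y = hi
    c(1, 3, 4), c(1, 4, 2),  # z = lo
    c(5, 6, 8), c(5, 8, 7)   # z = hi
  )
  surface_mesh(v, f)
}

#' @rdname mesh_box
#' @param radius,length Cylinder radius and length (mm).
#' @param axis Unit axis direction.
#' @param anchor Centre of the distal cap; the cylinder spans
#'   `anchor - length * axis` to `anchor`.
#' @param n_segments Circumferential tessellation.
#' @export
mesh_cylinder <- function(radius, length, axis = c(0, 0, 1),
                          anchor = c(0, 0, 0), n_segments = 64) {
  if (radius <= 0 || length <= 0) abort("radius and length must be > 0")
  axis <- axis / sqrt(sum(axis^2))
  th <- seq(0, 2 * pi, length.out = n_segments + 1)[-(n_segments + 1)]
  ring <- cbind(cos(th), sin(th)) * radius
  # orthonormal frame around axis
  up <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- cross3(matrix(axis, 1), matrix(up, 1))
  u <- u / sqrt(sum(u^2))
  w <- cross3(matrix(axis, 1), u)
  base_c <- anchor - length * axis
  ring3 <- ring[, 1] %o% as.vector(u) + ring[, 2] %o% as.vector(w)
  v_bot <- sweep(ring3, 2, base_c, "+")
  v_top <- sweep(ring3, 2, anchor, "+")
  v <- rbind(v_bot, v_top, base_c, anchor)
  n <- n_segments
  i <- seq_len(n); j <- c(2:n, 1)
  side <- rbind(cbind(i, j, n + j), cbind(i, n + j, n + i))
  cap_bot <- cbind(2 * n + 1, j, i)
  cap_top <- cbind(2 * n + 2, n + i, n + j)
  surface_mesh(v, rbind(side, cap_bot, cap_top))
}

#' @rdname mesh_box
#' @param n_subdiv Number of icosahedron subdivision rounds.
#' @export
mesh_icosphere <- function(radius = 1, n_subdiv = 2) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(n_subdiv)) {
    nv <- nrow(v)
    edge_mid <- new.env()
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- edge_mid[[key]]
      if (is.null(idx)) {
        v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
        idx <- nrow(v)
        edge_mid[[key]] <- idx
      }
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (r in seq_len(nrow(f))) {
      a <- f[r, 1]; b <- f[r, 2]; c_ <- f[r, 3]
      ab <- mid(a, b); bc <- mid(b, c_); ca <- mid(c_, a)
      newf[(r - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  surface_mesh(v, f)
}
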