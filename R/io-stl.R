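#' Read and write STL files
#'
#' Binary STL is little-endian with an 80-byte header; facet normals are
#' recomputed from the vertex winding on write and ignored on read.
#' Reading merges coincident vertices (1e-5 mm), so
#' `read_stl(write_stl(m))` reproduces vertex coordinates to binary
#' float precision.
#'
#' @param mesh A [surface_mesh()] (non-empty).
#' @param path File path.
#' @param mode `"binary"` (default) or `"ascii"`.
#' @return `write_stl()` returns `path` invisibly; `read_stl()` returns a
#'   [surface_mesh()].
#' @export
write_stl <- function(mesh, path, mode = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "surface_mesh"))
  mode <- match.arg(mode)
  if (nrow(mesh$faces) == 0) abort("cannot write an empty mesh")
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  n <- cross3(b - a, c_ - a)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len

  if (mode == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid applicatr", con)
    tri <- sprintf(
      "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
      n[, 1], n[, 2], n[, 3],
      a[, 1], a[, 2], a[, 3],
      b[, 1], b[, 2], b[, 3],
      c_[, 1], c_[, 2], c_[, 3])
    writeLines(tri, con)
    writeLines("endsolid applicatr", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(formatC("applicatr binary STL (unit: mm)",
                                width = -80))
    writeBin(header[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    dat <- t(cbind(n, a, b, c_))  # 12 floats per facet, column = facet
    block <- writeBin(as.vector(dat), raw(), size = 4, endian = "little")
    block <- matrix(block, nrow = 48)
    block <- rbind(block, matrix(as.raw(0), 2, ncol(block)))
    writeBin(as.vector(block), con)
  }
  invisible(path)
}

#' @rdname write_stl
#' @param merge_tol Vertex merge tolerance in mm.
#' @export
read_stl <- function(path, merge_tol = 1e-5) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  head <- readBin(path, "raw", n = 5)
  is_ascii <- identical(rawToChar(head), "solid") && is_ascii_stl(path)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0) abort("unreadable or empty STL file")
  nf <- nrow(tri) / 3
  merge_mesh_vertices(tri, matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE),
                      tol = merge_tol)
}

# Binary files can also start with "solid": confirm the ASCII structure.
is_ascii_stl <- function(path) {
  txt <- suppressWarnings(readLines(path, n = 20, skipNul = TRUE))
  any(grepl("facet|endsolid", txt))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path)
  vx <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vx) == 0 || length(vx) %% 3 != 0)
    abort("unreadable ASCII STL: vertex count not a multiple of 3")
  m <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  if (any(is.na(m))) abort("unreadable ASCII STL: malformed vertex line")
  m
}

read_stl_binary <- function(path) {
  sz <- file.size(path)
  if (sz < 84) abort("unreadable STL: file too short")
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", size = 4, endian = "little")
  if (nf <= 0 || sz < 84 + 50 * nf)
    abort("unreadable binary STL: facet count does not match file size")
  bytes <- readBin(con, "raw", n = 50 * nf)
  block <- matrix(bytes, nrow = 50)
  floats <- readBin(as.vector(block[1:48, ]), "double", n = 12 * nf,
                    size = 4, endian = "little")
  per <- matrix(floats, nrow = 12)  # normal + 3 vertices per facet
  tri <- rbind(t(per[4:6, , drop = FALSE]),
               t(per[7:9, , drop = FALSE]),
               t(per[10:12, , drop = FALSE]))
  # interleave back to a,b,c per facet
  idx <- as.vector(t(matrix(seq_len(3 * nf), ncol = 3)))
  tri[idx, , drop = FALSE]
}
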