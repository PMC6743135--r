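#' Contour sets and waypoint lists
#'
#' A `contour_set` holds labelled stacks of planar closed polygons in
#' patient coordinates (mm), the unit of RT-structure exchange. Each
#' structure is a list of slices; each slice is an n x 3 matrix of polygon
#' vertices (the closing edge is implicit). Structures can alternatively
#' be open polylines (geometric type `"open"`), used for manually
#' indicated needle-channel waypoints; those are exempt from the planarity
#' requirement and their point order is preserved verbatim.
#'
#' Coordinates are millimetres in the DICOM patient coordinate system as
#' stored (LPS); no axis flips are applied anywhere in the pipeline.
#'
#' @param structures Named list; each element a list of slice matrices
#'   (n x 3; n >= 3 for closed planar contours, n >= 1 for open
#'   polylines).
#' @param frame_of_reference Text identifier for the frame of reference.
#' @param slice_normal Unit 3-vector normal to the contour planes.
#' @param types Named character vector giving the geometric type per
#'   structure, `"closed_planar"` (default) or `"open"`. Unnamed scalar
#'   recycles to all structures.
#' @return A `contour_set` object.
#' @export
contour_set <- function(structures, frame_of_reference = "",
                        slice_normal = c(0, 0, 1), types = "closed_planar") {
  if (is.null(names(structures)) || anyDuplicated(names(structures)) ||
      any(names(structures) == ""))
    abort("structure labels must be unique and non-empty")
  slice_normal <- slice_normal / sqrt(sum(slice_normal^2))
  if (is.null(names(types))) {
    types <- setNames(rep(types, length(structures)), names(structures))
  } else {
    full <- setNames(rep("closed_planar", length(structures)),
                     names(structures))
    full[names(types)] <- types
    types <- full
  }
  stopifnot(all(types %in% c("closed_planar", "open")))
  structures <- purrr::imap(structures, function(slices, label) {
    slices <- lapply(slices, validate_slice, normal = slice_normal,
                     type = types[[label]], label = label)
    if (types[[label]] == "closed_planar") {
      pos <- vapply(slices, function(p) mean(p %*% slice_normal), numeric(1))
      slices <- slices[order(pos)]
    }
    slices
  })
  structure(
    list(structures = structures, types = types,
         frame_of_reference = frame_of_reference,
         slice_normal = slice_normal),
    class = "contour_set"
  )
}

validate_slice <- function(p, normal, type, label = NULL, tol = 1e-6) {
  p <- as.matrix(p)
  if (ncol(p) != 3)
    abort("contour points must have 3 coordinates")
  storage.mode(p) <- "double"
  if (!all(is.finite(p))) abort("contour points must be finite")
  if (type == "closed_planar") {
    if (nrow(p) < 3)
      abort("each closed contour polygon needs >= 3 points")
    d <- p %*% normal
    if (diff(range(d)) > tol)
      abort(paste0("non-planar contour",
                   if (!is.null(label)) paste0(" in ROI '", label, "'"),
                   ": spread along slice normal ",
                   format(diff(range(d))), " mm exceeds ", tol, " mm"))
  }
  p
}

#' @export
print.contour_set <- function(x, ...) {
  cat("<contour_set> ", length(x$structures), " structure(s)\n", sep = "")
  for (nm in names(x$structures)) {
    sl <- x$structures[[nm]]
    cat("  ", nm, " [", x$types[[nm]], "]: ", length(sl), " slice(s), ",
        sum(vapply(sl, nrow, integer(1))), " points\n", sep = "")
  }
  invisible(x)
}

#' @describeIn contour_set Flatten to a tibble with one row per vertex
#'   (columns `structure`, `slice`, `x`, `y`, `z`).
#' @param x A `contour_set`.
#' @param ... Unused.
#' @export
as_tibble.contour_set <- function(x, ...) {
  purrr::imap_dfr(x$structures, function(slices, label) {
    purrr::imap_dfr(slices, function(p, i) {
      tibble::tibble(structure = label, slice = i,
                     x = p[, 1], y = p[, 2], z = p[, 3])
    })
  })
}

#' Construct a channel waypoint list
#'
#' @param label Channel label.
#' @param points Ordered matrix (>= 2 x 3) of waypoints in mm.
#' @param role One of `"intracavitary"`, `"interstitial"`, `"loop"`.
#' @return A `waypoint_list` object.
#' @export
waypoint_list <- function(label, points,
                          role = c("intracavitary", "interstitial", "loop")) {
  role <- match.arg(role)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3 || nrow(points) < 2)
    abort("waypoints must be an n x 3 matrix with n >= 2")
  sep <- sqrt(rowSums(diff(points)^2))
  if (any(sep <= 1e-9))
    abort(paste0("duplicate consecutive waypoints in '", label, "'"))
  structure(list(label = label, points = points, role = role),
            class = "waypoint_list")
}

#' @export
print.waypoint_list <- function(x, ...) {
  cat("<waypoint_list> '", x$label, "' (", x$role, "), ",
      nrow(x$points), " points\n", sep = "")
  invisible(x)
}

ROLE_SUFFIXES <- c("_ic" = "intracavitary", "_int" = "interstitial",
                   "_loop" = "loop")

role_from_label <- function(label) {
  for (suf in names(ROLE_SUFFIXES)) {
    if (endsWith(label, suf)) return(unname(ROLE_SUFFIXES[suf]))
  }
  warn(paste0("label '", label, "' has no recognised role suffix ",
              "(_ic, _int, _loop); defaulting to intracavitary"))
  "intracavitary"
}

#' Extract planned channel waypoints from a contour set
#'
#' Structures whose label starts with `label_prefix` are interpreted as
#' manually indicated needle-channel polylines (all slices concatenated in
#' stored order, point order preserved). The channel role is parsed from
#' the label suffix: `_ic` intracavitary, `_int` interstitial, `_loop`
#' loop; an unknown suffix defaults to intracavitary with a warning.
#'
#' @param contours A [contour_set()].
#' @param label_prefix Prefix selecting channel structures.
#' @return A list of [waypoint_list()] objects (empty, with a warning, if
#'   nothing matches).
#' @export
extract_waypoints <- function(contours, label_prefix) {
  stopifnot(inherits(contours, "contour_set"))
  labels <- names(contours$structures)
  hit <- labels[startsWith(labels, label_prefix)]
  if (length(hit) == 0) {
    warn(paste0("no structure label starts with '", label_prefix, "'"))
    return(list())
  }
  lapply(hit, function(lb) {
    pts <- do.call(rbind, contours$structures[[lb]])
    waypoint_list(lb, pts, role_from_label(lb))
  })
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
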