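#' Plain-text contour fixture dialect
#'
#' A line-oriented exchange format for contour sets so that the whole
#' pipeline can be exercised without DICOM files: a short header
#' (`frame_of_reference`, `slice_normal`), then one block per structure
#' introduced by `structure: <label>` and `type: <closed_planar|open>`,
#' with one `x y z` point per line and a blank line between slices.
#'
#' @param x A [contour_set()].
#' @param path File path.
#' @return `write_fixture_contours()` returns `path` invisibly;
#'   `read_fixture_contours()` returns a [contour_set()].
#' @export
write_fixture_contours <- function(x, path) {
  stopifnot(inherits(x, "contour_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# applicatr contour fixture v1",
               paste("frame_of_reference:", x$frame_of_reference),
               paste("slice_normal:",
                     paste(format(x$slice_normal, digits = 15),
                           collapse = " "))), con)
  for (nm in names(x$structures)) {
    writeLines(c("", paste("structure:", nm),
                 paste("type:", x$types[[nm]])), con)
    slices <- x$structures[[nm]]
    for (i in seq_along(slices)) {
      if (i > 1) writeLines("", con)
      writeLines(apply(format(slices[[i]], digits = 15, trim = TRUE,
                              scientific = FALSE),
                       1, paste, collapse = " "), con)
    }
  }
  invisible(path)
}

#' @rdname write_fixture_contours
#' @export
read_fixture_contours <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  kv <- function(key, default = "") {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(hit) == 0) return(default)
    trimws(sub(paste0("^", key, ":"), "", hit[1]))
  }
  frame <- kv("frame_of_reference")
  normal <- as.numeric(strsplit(kv("slice_normal", "0 0 1"), "\\s+")[[1]])
  starts <- grep("^structure:", lines)
  if (length(starts) == 0) abort("no 'structure:' blocks found: format error")
  ends <- c(starts[-1] - 1, length(lines))
  structures <- list()
  types <- character()
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    label <- trimws(sub("^structure:", "", block[1]))
    type <- "closed_planar"
    body <- block[-1]
    if (length(body) && grepl("^type:", body[1])) {
      type <- trimws(sub("^type:", "", body[1]))
      body <- body[-1]
    }
    # split slices on blank lines
    blank <- trimws(body) == ""
    grp <- cumsum(blank)
    slices <- lapply(split(body[!blank], grp[!blank]), function(ls) {
      m <- do.call(rbind, lapply(strsplit(trimws(ls), "\\s+"), as.numeric))
      if (any(is.na(m)) || ncol(m) != 3)
        abort(paste0("malformed point line in structure '", label, "'"))
      m
    })
    names(slices) <- NULL
    structures[[label]] <- slices
    types[label] <- type
  }
  contour_set(structures, frame_of_reference = frame,
              slice_normal = normal, types = types)
}

#' Read or write channel waypoint files
#'
#' One file per channel, one `x y z` point per line, mirroring the
#' TEXT-file intermediate used between segmentation and CAD. Label and
#' role are carried in comment headers and fall back to the file name.
#'
#' @param x A [waypoint_list()].
#' @param path File path.
#' @return `write_waypoints()` returns `path` invisibly;
#'   `read_waypoints()` returns a [waypoint_list()].
#' @export
write_waypoints <- function(x, path) {
  stopifnot(inherits(x, "waypoint_list"))
  writeLines(c(paste("# label:", x$label), paste("# role:", x$role),
               apply(format(x$points, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     1, paste, collapse = " ")),
             path)
  invisible(path)
}

#' @rdname write_waypoints
#' @export
read_waypoints <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (length(hit) == 0) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  label <- get_meta("label", tools::file_path_sans_ext(basename(path)))
  role <- get_meta("role", "intracavitary")
  body <- lines[!grepl("^#", lines) & trimws(lines) != ""]
  pts <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  waypoint_list(label, pts, role)
}
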