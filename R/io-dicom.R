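## Minimal DICOM RT-structure support: explicit-VR little-endian, contour
## attributes only. Enough to write conformant fixture files and to read
## the contour payload of an RTSTRUCT back into a contour_set; not a
## general DICOM implementation.

SOP_CLASS_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1"
IMPL_CLASS_UID <- "1.2.826.0.1.3680043.10.424.1"

raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")
raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                endian = "little")

pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

dcm_element <- function(group, element, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(paste(value, collapse = "\\"))
    value <- pad_even(value, if (vr == "UI") as.raw(0) else as.raw(0x20))
  }
  head <- c(raw_u16(group), raw_u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), raw_u32(length(value)), value)
  } else {
    if (length(value) > 65534) abort("element value too long for short VR")
    c(head, raw_u16(length(value)), value)
  }
}

dcm_item <- function(body) {
  c(raw_u16(0xFFFE), raw_u16(0xE000), raw_u32(length(body)), body)
}

dcm_sequence <- function(group, element, items) {
  dcm_element(group, element, "SQ", do.call(c, c(items, list(raw(0)))))
}

format_ds <- function(x) {
  format(x, digits = 10, scientific = FALSE, trim = TRUE)
}

#' Write a contour set as a minimal DICOM RT-structure file
#'
#' Produces an explicit-VR little-endian RTSTRUCT object carrying the
#' structure-set ROI and contour sequences (labels, geometric types,
#' contour data). Intended for generating test fixtures for the import
#' path; it is not a full structure-set writer.
#'
#' @param x A [contour_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_rtstruct <- function(x, path) {
  stopifnot(inherits(x, "contour_set"))
  frame_uid <- if (grepl("^[0-9.]+$", x$frame_of_reference) &&
                   nzchar(x$frame_of_reference)) {
    x$frame_of_reference
  } else {
    "1.2.826.0.1.3680043.10.424.2"
  }
  sop_instance <- "1.2.826.0.1.3680043.10.424.3"

  labels <- names(x$structures)
  roi_items <- lapply(seq_along(labels), function(i) {
    dcm_item(c(
      dcm_element(0x3006, 0x0022, "IS", as.character(i)),
      dcm_element(0x3006, 0x0024, "UI", frame_uid),
      dcm_element(0x3006, 0x0026, "LO", labels[i])
    ))
  })
  contour_items <- lapply(seq_along(labels), function(i) {
    slices <- x$structures[[labels[i]]]
    type <- if (x$types[[labels[i]]] == "closed_planar") "CLOSED_PLANAR"
            else "OPEN_NONPLANAR"
    slice_items <- lapply(slices, function(p) {
      dcm_item(c(
        dcm_element(0x3006, 0x0042, "CS", type),
        dcm_element(0x3006, 0x0046, "IS", as.character(nrow(p))),
        dcm_element(0x3006, 0x0050, "DS",
                    paste(format_ds(as.vector(t(p))), collapse = "\\"))
      ))
    })
    dcm_item(c(
      dcm_sequence(0x3006, 0x0040, slice_items),
      dcm_element(0x3006, 0x0084, "IS", as.character(i))
    ))
  })

  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", SOP_CLASS_RTSTRUCT),
    dcm_element(0x0008, 0x0018, "UI", sop_instance),
    dcm_element(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_element(0x3006, 0x0002, "SH", "applicatr fixture"),
    dcm_sequence(0x3006, 0x0010, list(dcm_item(
      dcm_element(0x0020, 0x0052, "UI", frame_uid)
    ))),
    dcm_sequence(0x3006, 0x0020, roi_items),
    dcm_sequence(0x3006, 0x0039, contour_items)
  )

  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", SOP_CLASS_RTSTRUCT),
    dcm_element(0x0002, 0x0003, "UI", sop_instance),
    dcm_element(0x0002, 0x0010, "UI", TRANSFER_SYNTAX_ELE),
    dcm_element(0x0002, 0x0012, "UI", IMPL_CLASS_UID)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", raw_u32(length(meta_body))),
            meta_body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

## --- reading -------------------------------------------------------------

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_u16 <- function(bytes, at) {
  sum(as.integer(bytes[at:(at + 1)]) * c(1, 256))
}
read_u32 <- function(bytes, at) {
  sum(as.numeric(bytes[at:(at + 3)]) * c(1, 256, 65536, 16777216))
}

# Parse explicit-VR little-endian elements in bytes[at..end] into a list
# of (group, element, vr, value) where SQ values are lists of item lists.
parse_dcm <- function(bytes, at, end) {
  out <- list()
  while (at <= end) {
    group <- read_u16(bytes, at); element <- read_u16(bytes, at + 2)
    if (group == 0xFFFE) {  # delimiter reached inside undefined lengths
      break
    }
    vr <- rawToChar(bytes[(at + 4):(at + 5)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(bytes, at + 8); at <- at + 12
    } else {
      len <- read_u16(bytes, at + 6); at <- at + 8
    }
    if (vr == "SQ") {
      if (len == 4294967295) {
        parsed <- parse_sq_items(bytes, at, end, undefined = TRUE)
      } else {
        parsed <- parse_sq_items(bytes, at, at + len - 1, undefined = FALSE)
      }
      value <- parsed$items
      at <- parsed$at
    } else {
      value <- if (len > 0) bytes[at:(at + len - 1)] else raw(0)
      at <- at + len
    }
    out[[length(out) + 1]] <- list(group = group, element = element,
                                   vr = vr, value = value)
  }
  list(elements = out, at = at)
}

parse_sq_items <- function(bytes, at, end, undefined) {
  items <- list()
  repeat {
    if (at > end) break
    group <- read_u16(bytes, at); element <- read_u16(bytes, at + 2)
    len <- read_u32(bytes, at + 4)
    at <- at + 8
    if (group == 0xFFFE && element == 0xE0DD) break  # sequence delimiter
    if (!(group == 0xFFFE && element == 0xE000))
      abort("malformed DICOM sequence: expected item tag")
    if (len == 4294967295) {
      parsed <- parse_dcm(bytes, at, end)
      at <- parsed$at
      # consume item delimiter
      if (at <= end && read_u16(bytes, at) == 0xFFFE &&
          read_u16(bytes, at + 2) == 0xE00D) at <- at + 8
    } else {
      parsed <- parse_dcm(bytes, at, at + len - 1)
      at <- at + len
    }
    items[[length(items) + 1]] <- parsed$elements
  }
  list(items = items, at = at)
}

dcm_find <- function(elements, group, element) {
  for (e in elements) {
    if (e$group == group && e$element == element) return(e)
  }
  NULL
}

dcm_string <- function(elements, group, element, default = NULL) {
  e <- dcm_find(elements, group, element)
  if (is.null(e)) return(default)
  trimws(rawToChar(e$value[e$value != as.raw(0)]))
}

#' Read structure contours from an RT-structure or fixture file
#'
#' Accepts either a DICOM RT-structure object (modality RTSTRUCT,
#' explicit-VR little-endian) or the plain-text contour fixture dialect
#' (see [write_fixture_contours()]); the format is sniffed from the file
#' header. Polygon points are preserved verbatim in mm; slices of closed
#' structures are ordered ascending along the slice normal.
#'
#' @param path File path.
#' @return A [contour_set()] with one structure per ROI, in stored ROI
#'   order.
#' @export
read_rtstruct <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  head <- readBin(path, "raw", n = 132)
  if (length(head) >= 132 && rawToChar(head[129:132]) == "DICM") {
    read_rtstruct_dicom(path)
  } else {
    read_fixture_contours(path)
  }
}

read_rtstruct_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  top <- parse_dcm(bytes, 133, length(bytes))$elements
  modality <- dcm_string(top, 0x0008, 0x0060)
  if (is.null(modality) || modality != "RTSTRUCT")
    abort("not an RT-structure object (modality is not RTSTRUCT)")

  roi_seq <- dcm_find(top, 0x3006, 0x0020)
  contour_seq <- dcm_find(top, 0x3006, 0x0039)
  if (is.null(roi_seq) || is.null(contour_seq))
    abort("missing StructureSetROISequence or ROIContourSequence: format error")

  frame <- ""
  ref_for <- dcm_find(top, 0x3006, 0x0010)
  if (!is.null(ref_for) && length(ref_for$value) > 0)
    frame <- dcm_string(ref_for$value[[1]], 0x0020, 0x0052, "") %||% ""

  roi_names <- character()
  for (item in roi_seq$value) {
    num <- dcm_string(item, 0x3006, 0x0022)
    nm <- dcm_string(item, 0x3006, 0x0026, paste0("roi_", num))
    roi_names[num] <- nm
  }

  structures <- list()
  types <- character()
  order_labels <- character()
  for (item in contour_seq$value) {
    num <- dcm_string(item, 0x3006, 0x0084)
    label <- roi_names[[num]] %||% paste0("roi_", num)
    cs <- dcm_find(item, 0x3006, 0x0040)
    slices <- list()
    type <- "closed_planar"
    if (!is.null(cs)) {
      for (ct in cs$value) {
        gtype <- dcm_string(ct, 0x3006, 0x0042, "CLOSED_PLANAR")
        if (gtype != "CLOSED_PLANAR") type <- "open"
        data <- dcm_string(ct, 0x3006, 0x0050)
        vals <- as.numeric(strsplit(data, "\\\\")[[1]])
        if (length(vals) %% 3 != 0)
          abort(paste0("contour data length not a multiple of 3 in ROI '",
                       label, "'"))
        slices[[length(slices) + 1]] <- matrix(vals, ncol = 3, byrow = TRUE)
      }
    }
    structures[[label]] <- slices
    types[label] <- type
    order_labels <- c(order_labels, label)
  }
  structures <- structures[order_labels]

  normal <- infer_slice_normal(structures, types)
  contour_set(structures, frame_of_reference = frame,
              slice_normal = normal, types = types)
}

# Closed contours are planar: pick the coordinate axis with (near-)zero
# in-polygon spread as the slice normal. Defaults to z.
infer_slice_normal <- function(structures, types) {
  for (label in names(structures)) {
    if (types[[label]] != "closed_planar") next
    for (p in structures[[label]]) {
      spread <- apply(p, 2, function(v) diff(range(v)))
      if (sum(spread < 1e-6) >= 1) {
        ax <- which.min(spread)
        return(as.numeric(seq_len(3) == ax))
      }
    }
  }
  c(0, 0, 1)
}
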