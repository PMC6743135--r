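test_that("fixture dialect round-trips a contour set exactly", {
  cs <- contour_set(
    list(vault = list(square_polygon(10, 0), square_polygon(10, 5)),
         needle_01_int = list(rbind(c(1, 1, 0), c(1.5, 2, 5), c(2, 3, 9))),
         organ = list(square_polygon(4, 2) + 20)),
    frame_of_reference = "FOR-A",
    types = c(needle_01_int = "open"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_fixture_contours(cs, path)
  back <- read_fixture_contours(path)
  expect_identical(names(back$structures), names(cs$structures))
  expect_identical(back$frame_of_reference, "FOR-A")
  expect_identical(unname(back$types), unname(cs$types))
  for (nm in names(cs$structures)) {
    for (i in seq_along(cs$structures[[nm]])) {
      expect_lt(max(abs(back$structures[[nm]][[i]] -
                          cs$structures[[nm]][[i]])), 1e-6)
    }
  }
})

test_that("reading a square contour preserves points verbatim", {
  cs <- contour_set(list(sq = list(square_polygon(10), square_polygon(10, 4))))
  path <- withr::local_tempfile(fileext = ".txt")
  write_fixture_contours(cs, path)
  back <- read_rtstruct(path)
  expect_length(back$structures, 1)
  expect_equal(nrow(back$structures$sq[[1]]), 4)
  # never reorders points within a polygon
  expect_equal(back$structures$sq[[1]], square_polygon(10))
})

test_that("synthetic vault fixture survives a write-read round trip", {
  cs <- synth_topography(topography_params(seed = 1))
  path <- withr::local_tempfile(fileext = ".txt")
  write_fixture_contours(cs, path)
  back <- read_rtstruct(path)
  expect_equal(length(back$structures$vault), length(cs$structures$vault))
  dev <- max(mapply(function(a, b) max(abs(a - b)),
                    back$structures$vault, cs$structures$vault))
  expect_lt(dev, 1e-6)
})

test_that("minimal RTSTRUCT writer round-trips through the reader", {
  cs <- contour_set(
    list(vault = list(square_polygon(10, 0), square_polygon(10, 5)),
         target = list(square_polygon(6, 2)),
         needle_01_int = list(rbind(c(1, 1, 0), c(1, 2, 5), c(2, 3, 9)))),
    frame_of_reference = "1.2.840.10008.999.1",
    types = c(needle_01_int = "open"))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_fixture_rtstruct(cs, path)
  back <- read_rtstruct(path)
  expect_identical(names(back$structures), names(cs$structures))
  expect_identical(back$frame_of_reference, "1.2.840.10008.999.1")
  expect_lt(max(abs(back$structures$vault[[2]] - cs$structures$vault[[2]])),
            1e-6)
  expect_identical(back$types[["needle_01_int"]], "open")
})

test_that("pydicom parses the fixture RTSTRUCT (independent oracle)", {
  cs <- contour_set(list(vault = list(square_polygon(10))),
                    frame_of_reference = "1.2.3.4")
  path <- withr::local_tempfile(fileext = ".dcm")
  write_fixture_rtstruct(cs, path)
  script <- paste0(
    "import pydicom; ds = pydicom.dcmread('", path, "'); ",
    "print(ds.Modality); ",
    "print(ds.StructureSetROISequence[0].ROIName); ",
    "print(len(ds.ROIContourSequence[0].ContourSequence[0].ContourData))")
  out <- tryCatch(
    system2("python", c("-c", shQuote(script)), stdout = TRUE,
            stderr = TRUE),
    error = function(e) NULL)
  expect_false(is.null(out))
  expect_identical(out[1], "RTSTRUCT")
  expect_identical(out[2], "vault")
  expect_identical(out[3], "12")
})

test_that("non-RTSTRUCT DICOM and malformed files raise format errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("no structures here"), path)
  expect_error(read_rtstruct(path), "format error")
  expect_error(read_rtstruct(file.path(tempdir(), "missing-file.dcm")),
               "not found")
})

test_that("extract_waypoints selects, orders and roles channels", {
  cs <- contour_set(
    list(needle_01_int = list(rbind(c(0, 0, 0), c(0, 1, 5), c(1, 2, 9))),
         needle_02_ic = list(rbind(c(5, 0, 0), c(5, 1, 5))),
         vault = list(square_polygon(10))),
    types = c(needle_01_int = "open", needle_02_ic = "open"))
  wls <- extract_waypoints(cs, "needle")
  expect_length(wls, 2)
  expect_identical(wls[[1]]$role, "interstitial")
  expect_identical(wls[[2]]$role, "intracavitary")
  expect_equal(nrow(wls[[1]]$points), 3)
  expect_equal(wls[[1]]$points[, 3], c(0, 5, 9))

  expect_warning(empty <- extract_waypoints(cs, "nope"), "no structure")
  expect_length(empty, 0)

  cs2 <- contour_set(list(needle_03_xyz = list(rbind(c(0, 0, 0), c(1, 1, 1)))),
                     types = "open")
  expect_warning(w3 <- extract_waypoints(cs2, "needle"), "role suffix")
  expect_identical(w3[[1]]$role, "intracavitary")
})

test_that("waypoint counts survive extraction from a multi-channel fixture", {
  withr::with_seed(42, {
    npts <- sample(4:9, 5, replace = TRUE)
    structures <- lapply(npts, function(n) {
      list(cbind(runif(n), runif(n), sort(runif(n, 0, 50))))
    })
    names(structures) <- sprintf("needle_%02d_int", 1:5)
    cs <- contour_set(structures, types = "open")
    wls <- extract_waypoints(cs, "needle")
    expect_length(wls, 5)
    expect_equal(vapply(wls, function(w) nrow(w$points), integer(1)), npts)
  })
})

test_that("waypoint files round-trip with label and role", {
  wp <- waypoint_list("needle_07_loop", rbind(c(0, 0, 0), c(1, 2, 3),
                                              c(4, 5, 9)), role = "loop")
  path <- withr::local_tempfile(fileext = ".txt")
  write_waypoints(wp, path)
  back <- read_waypoints(path)
  expect_identical(back$label, wp$label)
  expect_identical(back$role, "loop")
  expect_lt(max(abs(back$points - wp$points)), 1e-9)
})

test_that("contour validation rejects bad polygons", {
  expect_error(contour_set(list(bad = list(rbind(c(0, 0, 0), c(1, 0, 0))))),
               ">= 3 points")
  nonplanar <- rbind(c(0, 0, 0), c(1, 0, 0.001), c(1, 1, 0), c(0, 1, 0))
  expect_error(contour_set(list(roi_x = list(nonplanar))),
               "non-planar.*roi_x")
  expect_error(waypoint_list("dup", rbind(c(0, 0, 0), c(0, 0, 0))),
               "duplicate")
})
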