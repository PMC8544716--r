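test_that("localization tables survive a write/read round trip", {
  locs <- loc_tbl(c(0.123456, -512.5, 1e4), c(1, 2, 3), c(-50.25, 0, 50),
                  channel = c("sRNA", "mRNA", "sRNA"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_localizations(locs, path)
  back <- read_localizations(path)
  expect_equal(back$x, locs$x, tolerance = 1e-6)
  expect_equal(back$y, locs$y, tolerance = 1e-6)
  expect_equal(back$z, locs$z, tolerance = 1e-6)
  expect_identical(back$frame, locs$frame)
  expect_identical(back$channel, locs$channel)
})

test_that("a header-only file reads as an empty table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines('"x [nm]","y [nm]","z [nm]","frame","channel"', path)
  expect_equal(nrow(read_localizations(path)), 0)
})

test_that("format and parse errors name the offending column and row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"x [nm]","y [nm]","frame","channel"', '1,2,0,sRNA'), path)
  expect_error(read_localizations(path), 'z \\[nm\\]',
               class = "smcoloc_format_error")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('"x [nm]","y [nm]","z [nm]","frame","channel"',
               '1,2,3,0,sRNA', '1,oops,3,1,sRNA'), path2)
  expect_error(read_localizations(path2), "row 2",
               class = "smcoloc_parse_error")
})

test_that("custom dialects map alternative column headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("xnm,ynm,znm,t,ch", "5,6,7,0,mRNA"), path)
  d <- c(x = "xnm", y = "ynm", z = "znm", frame = "t", channel = "ch")
  locs <- read_localizations(path, dialect = d)
  expect_equal(locs$x, 5)
  expect_equal(locs$channel, "mRNA")
})

test_that("box containment assigns ids and leaves outsiders unassigned", {
  rois <- roi_box(7L, -10, 10, -10, 10, -10, 10)
  locs <- loc_tbl(c(0, 100), c(0, 100), c(0, 100))
  out <- assign_to_cells(locs, rois)
  expect_identical(out$cell_id, c(7L, NA))
  expect_identical(out$x, locs$x)   # coordinates untouched
})

test_that("assignment equals a brute-force point-in-box scan", {
  set.seed(101)
  rois <- dplyr::bind_rows(lapply(1:5, function(i) {
    x0 <- (i - 1) * 300
    roi_box(i, x0, x0 + 100, 0, 100, 0, 100)
  }))
  locs <- loc_tbl(runif(1000, -100, 1600), runif(1000, -50, 150),
                  runif(1000, -50, 150))
  out <- assign_to_cells(locs, rois)
  brute <- vapply(seq_len(1000), function(j) {
    hit <- which(locs$x[j] >= rois$xmin & locs$x[j] <= rois$xmax &
                   locs$y[j] >= rois$ymin & locs$y[j] <= rois$ymax &
                   locs$z[j] >= rois$zmin & locs$z[j] <= rois$zmax)
    if (length(hit) == 0) NA_integer_ else rois$cell_id[hit[1]]
  }, integer(1))
  expect_identical(out$cell_id, brute)
  expect_equal(sum(!is.na(out$cell_id)) + sum(is.na(out$cell_id)),
               nrow(locs))
})

test_that("overlapping ROIs are rejected", {
  rois <- dplyr::bind_rows(roi_box(1, 0, 10, 0, 10, 0, 10),
                           roi_box(2, 5, 15, 0, 10, 0, 10))
  expect_error(assign_to_cells(loc_tbl(1, 1, 1), rois),
               class = "smcoloc_config_error")
})

test_that("spherocylinder containment follows the axis-segment distance", {
  roi <- roi_spherocylinder(1, 0, 0, 0, length = 1000, radius = 100)
  pts <- rbind(c(0, 0, 0),        # centre
               c(500, 0, 0),      # shaft end on axis
               c(599, 0, 0),      # inside the cap
               c(601, 0, 0),      # just past the cap
               c(0, 99, 0),       # inside radially
               c(0, 101, 0))      # outside radially
  out <- assign_to_cells(loc_tbl(pts[, 1], pts[, 2], pts[, 3]), roi)
  expect_identical(out$cell_id, c(1L, 1L, 1L, NA, 1L, NA))
  vol <- roi_volume(roi)
  expect_equal(vol, pi * 100^2 * 1000 + 4 / 3 * pi * 100^3)
})

test_that("ROI sets survive a JSON round trip", {
  rois <- dplyr::bind_rows(
    roi_box(1, 0, 10, 0, 10, 0, 10, strain_label = "WT"),
    roi_spherocylinder(2, 100, 0, 0, strain_label = "marker"))
  path <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, path)
  back <- read_rois(path)
  expect_equal(back$cell_id, rois$cell_id)
  expect_equal(back$radius, rois$radius)
  expect_equal(back$strain_label, rois$strain_label)
})
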