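#' Default column-name dialect for localization CSV files
#'
#' Maps the internal column names (`x`, `y`, `z`, `frame`, `channel`) to the
#' header names used in the CSV export. Positions are always interpreted in
#' nanometres.
#'
#' @return Named character vector mapping internal names to CSV header names.
#' @export
default_dialect <- function() {
  c(x = "x [nm]", y = "y [nm]", z = "z [nm]", frame = "frame",
    channel = "channel")
}

#' Read a 3D localization table
#'
#' Reads a CSV of single-fluorophore localizations (one row per blink event)
#' into a tibble with columns `x`, `y`, `z` (nm), `frame` and `channel`.
#' Unknown columns are ignored; row order is preserved.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Named character vector mapping internal column names to the
#'   file's header names; see [default_dialect()].
#' @return A tibble with columns `x`, `y`, `z`, `frame`, `channel` and
#'   `cell_id` (`NA` = unassigned).
#' @export
read_localizations <- function(path, dialect = default_dialect()) {
  stopifnot(is.character(path), length(path) == 1)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("localization file %s is missing required column(s): %s",
                  path, paste(sprintf('"%s"', missing_cols), collapse = ", ")),
          class = "smcoloc_format_error")
  }
  out <- tibble(
    x = parse_num_col(raw[[dialect[["x"]]]], dialect[["x"]]),
    y = parse_num_col(raw[[dialect[["y"]]]], dialect[["y"]]),
    z = parse_num_col(raw[[dialect[["z"]]]], dialect[["z"]]),
    frame = as.integer(parse_num_col(raw[[dialect[["frame"]]]],
                                     dialect[["frame"]])),
    channel = as.character(raw[[dialect[["channel"]]]])
  )
  if (any(out$frame < 0, na.rm = TRUE)) {
    abort("negative frame index in localization table",
          class = "smcoloc_format_error")
  }
  out$cell_id <- NA_integer_
  out
}

# strict numeric parse that reports the first offending row
parse_num_col <- function(chr, col_name) {
  if (length(chr) == 0) return(numeric(0))
  val <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(val) & !is.na(chr) & trimws(chr) != "" &
                 toupper(trimws(chr)) != "NA")
  if (length(bad) > 0) {
    abort(sprintf("non-numeric value \"%s\" in column \"%s\" at data row %d",
                  chr[bad[1]], col_name, bad[1]),
          class = "smcoloc_parse_error")
  }
  val
}

#' Write a localization table to CSV
#'
#' Inverse of [read_localizations()]: writes `x`, `y`, `z`, `frame`, `channel`
#' under the dialect's header names.
#'
#' @param locs Localization tibble.
#' @inheritParams read_localizations
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path, dialect = default_dialect()) {
  out <- tibble(locs$x, locs$y, locs$z, locs$frame, locs$channel)
  names(out) <- unname(dialect[c("x", "y", "z", "frame", "channel")])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Construct an axis-aligned box cell ROI
#'
#' @param cell_id Integer cell identifier, unique within a field of view.
#' @param xmin,xmax,ymin,ymax,zmin,zmax Box bounds in nm.
#' @param strain_label Free-text condition label (e.g. "WT", "dhfq",
#'   "marker").
#' @return One-row ROI tibble.
#' @export
roi_box <- function(cell_id, xmin, xmax, ymin, ymax, zmin, zmax,
                    strain_label = "") {
  stopifnot(xmax >= xmin, ymax >= ymin, zmax >= zmin)
  tibble(cell_id = as.integer(cell_id), shape = "box",
         xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
         zmin = zmin, zmax = zmax,
         cx = NA_real_, cy = NA_real_, cz = NA_real_,
         ax = NA_real_, ay = NA_real_, az = NA_real_,
         length = NA_real_, radius = NA_real_,
         strain_label = strain_label)
}

#' Construct a spherocylinder (rod-shaped cell) ROI
#'
#' A cylinder of length `length` and radius `radius` capped with hemispheres,
#' the standard idealization of a rod-shaped bacterium.
#'
#' @inheritParams roi_box
#' @param cx,cy,cz Centre of the rod (nm).
#' @param ax,ay,az Axis direction (normalized internally).
#' @param length Cylindrical (shaft) length in nm, >= 0.
#' @param radius Rod radius in nm, > 0.
#' @return One-row ROI tibble.
#' @export
roi_spherocylinder <- function(cell_id, cx, cy, cz, ax = 1, ay = 0, az = 0,
                               length = 2000, radius = 400,
                               strain_label = "") {
  stopifnot(length >= 0, radius > 0)
  nrm <- sqrt(ax^2 + ay^2 + az^2)
  stopifnot(nrm > 0)
  tibble(cell_id = as.integer(cell_id), shape = "spherocylinder",
         xmin = NA_real_, xmax = NA_real_, ymin = NA_real_, ymax = NA_real_,
         zmin = NA_real_, zmax = NA_real_,
         cx = cx, cy = cy, cz = cz,
         ax = ax / nrm, ay = ay / nrm, az = az / nrm,
         length = length, radius = radius,
         strain_label = strain_label)
}

#' ROI volume in nm^3
#'
#' @param roi One-row ROI tibble (box or spherocylinder).
#' @return Volume in nm^3.
#' @export
roi_volume <- function(roi) {
  stopifnot(nrow(roi) == 1)
  if (roi$shape == "box") {
    (roi$xmax - roi$xmin) * (roi$ymax - roi$ymin) * (roi$zmax - roi$zmin)
  } else {
    pi * roi$radius^2 * roi$length + 4 / 3 * pi * roi$radius^3
  }
}

# axis-aligned bounding box of any ROI, as c(xmin,xmax,ymin,ymax,zmin,zmax)
roi_bbox <- function(roi) {
  if (roi$shape == "box") {
    c(roi$xmin, roi$xmax, roi$ymin, roi$ymax, roi$zmin, roi$zmax)
  } else {
    h <- roi$length / 2
    ends <- rbind(
      c(roi$cx - h * roi$ax, roi$cy - h * roi$ay, roi$cz - h * roi$az),
      c(roi$cx + h * roi$ax, roi$cy + h * roi$ay, roi$cz + h * roi$az))
    c(min(ends[, 1]) - roi$radius, max(ends[, 1]) + roi$radius,
      min(ends[, 2]) - roi$radius, max(ends[, 2]) + roi$radius,
      min(ends[, 3]) - roi$radius, max(ends[, 3]) + roi$radius)
  }
}

# logical vector: which of the points (n x 3 matrix) fall inside the ROI
roi_contains <- function(roi, pts) {
  if (nrow(pts) == 0) return(logical(0))
  if (roi$shape == "box") {
    pts[, 1] >= roi$xmin & pts[, 1] <= roi$xmax &
      pts[, 2] >= roi$ymin & pts[, 2] <= roi$ymax &
      pts[, 3] >= roi$zmin & pts[, 3] <= roi$zmax
  } else {
    # distance to the axis segment <= radius
    h <- roi$length / 2
    a <- c(roi$ax, roi$ay, roi$az)
    d <- sweep(pts, 2, c(roi$cx, roi$cy, roi$cz))
    t <- pmin(pmax(d %*% a, -h), h)
    res <- d - outer(as.vector(t), a)
    rowSums(res^2) <= roi$radius^2
  }
}

#' Assign localizations to cell ROIs
#'
#' Fills the `cell_id` column: each localization receives the id of the ROI
#' containing it, or `NA` when it lies outside every ROI. ROIs must be
#' pairwise disjoint (checked on bounding boxes).
#'
#' @param locs Localization tibble (columns `x`, `y`, `z`).
#' @param rois ROI tibble built from [roi_box()] / [roi_spherocylinder()]
#'   rows.
#' @return `locs` with `cell_id` filled in; coordinates untouched.
#' @export
assign_to_cells <- function(locs, rois) {
  stopifnot(nrow(rois) >= 1)
  if (anyDuplicated(rois$cell_id)) {
    abort("duplicate cell_id in ROI set", class = "smcoloc_config_error")
  }
  bb <- t(vapply(seq_len(nrow(rois)), function(i) roi_bbox(rois[i, ]),
                 numeric(6)))
  n <- nrow(rois)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (bb[i, 1] < bb[j, 2] && bb[j, 1] < bb[i, 2] &&
            bb[i, 3] < bb[j, 4] && bb[j, 3] < bb[i, 4] &&
            bb[i, 5] < bb[j, 6] && bb[j, 5] < bb[i, 6]) {
          abort(sprintf("ROIs %d and %d overlap (bounding boxes intersect)",
                        rois$cell_id[i], rois$cell_id[j]),
                class = "smcoloc_config_error")
        }
      }
    }
  }
  pts <- as.matrix(locs[, c("x", "y", "z")])
  cell <- rep(NA_integer_, nrow(locs))
  for (i in seq_len(n)) {
    # bounding-box prefilter, exact containment test inside
    cand <- which(is.na(cell) &
                    pts[, 1] >= bb[i, 1] & pts[, 1] <= bb[i, 2] &
                    pts[, 2] >= bb[i, 3] & pts[, 2] <= bb[i, 4] &
                    pts[, 3] >= bb[i, 5] & pts[, 3] <= bb[i, 6])
    if (length(cand) > 0) {
      inside <- roi_contains(rois[i, ], pts[cand, , drop = FALSE])
      cell[cand[inside]] <- rois$cell_id[i]
    }
  }
  locs$cell_id <- cell
  locs
}

#' Write / read ROI sets as JSON
#'
#' @param rois ROI tibble.
#' @param path JSON file path.
#' @return `path` (write) or the ROI tibble (read).
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(rois, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  df <- jsonlite::fromJSON(path)
  num_cols <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax",
                "cx", "cy", "cz", "ax", "ay", "az", "length", "radius")
  for (cn in intersect(num_cols, names(df))) df[[cn]] <- as.numeric(df[[cn]])
  df$cell_id <- as.integer(df$cell_id)
  as_tibble(df)
}
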