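# I/O for B-scan images, annotation sidecars, profiles, topographies and
# cohort tables.
#
# Image convention: row 0 (R index 1) is the vitreous (top of the scan);
# axial depth increases with row index.  Lateral pixel positions are
# 0-based column indices.  Physical coordinates are micrometres:
# x = col * lateral_scale_um, y = row * axial_scale_um.  Exported distances
# are in mm, thicknesses in um.

VALID_AXES <- c(0, 45, 90, 135)

#' Construct a B-scan object
#'
#' A `bscan` couples a grayscale pixel grid with the physical calibration
#' and acquisition metadata needed to measure thickness in micrometres.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`; row 1 is the
#'   vitreous (top of the image).
#' @param lateral_scale_um Micrometres per pixel column (> 0).
#' @param axial_scale_um Micrometres per pixel row (> 0).
#' @param scan_width_mm Nominal scan line length in mm (default 8).
#' @param direction_axis_deg Cross-line axis, one of 0, 45, 90, 135 degrees.
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param signal_strength Integer device quality index; scans below 7 are
#'   flagged at validation and excluded at cohort assembly, never dropped
#'   at read time.
#' @return An object of class `bscan`.
#' @export
bscan <- function(pixels, lateral_scale_um, axial_scale_um,
                  scan_width_mm = 8, direction_axis_deg, eye,
                  signal_strength = 10L) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    pct_stop("pctopo_schema_error", "pixel grid must be non-empty")
  }
  if (!is_number(lateral_scale_um) || lateral_scale_um <= 0 ||
      !is_number(axial_scale_um) || axial_scale_um <= 0) {
    pct_stop("pctopo_schema_error", "pixel scales must be positive numbers")
  }
  if (!is_number(direction_axis_deg) || !direction_axis_deg %in% VALID_AXES) {
    pct_stop("pctopo_schema_error",
             "direction_axis_deg must be one of %s",
             paste(VALID_AXES, collapse = ", "))
  }
  if (!is.character(eye) || length(eye) != 1L || !eye %in% c("OD", "OS")) {
    pct_stop("pctopo_schema_error", "eye must be \"OD\" or \"OS\"")
  }
  if (!is_number(signal_strength)) {
    pct_stop("pctopo_schema_error", "signal_strength must be recorded")
  }
  structure(list(
    pixels = pixels,
    lateral_scale_um = as.numeric(lateral_scale_um),
    axial_scale_um = as.numeric(axial_scale_um),
    scan_width_mm = as.numeric(scan_width_mm),
    direction_axis_deg = as.numeric(direction_axis_deg),
    eye = eye,
    signal_strength = as.integer(signal_strength),
    low_signal = FALSE
  ), class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf(
    "<bscan> %d x %d px, %.3g x %.3g um/px, axis %g deg, %s, SS %d%s\n",
    nrow(x$pixels), ncol(x$pixels), x$axial_scale_um, x$lateral_scale_um,
    x$direction_axis_deg, x$eye, x$signal_strength,
    if (isTRUE(x$low_signal)) " [low signal]" else ""))
  invisible(x)
}

#' Construct a choroid boundary annotation
#'
#' Holds the manually marked choroid boundaries, the hand-drawn reference
#' curve (one branch per side of the disc, drawn parallel to Bruch's
#' membrane) and the two Bruch's membrane termini that define the disc
#' margin.  All coordinates are pixel `(col, row)` pairs.
#'
#' @param inner_boundary,outer_boundary Polylines (n x 2 matrices of
#'   `(col, row)`), x-monotone, with at least 3 vertices; the inner
#'   boundary lies above (smaller row) the outer boundary.
#' @param reference_points List of two polylines, the left-side and
#'   right-side reference curves.
#' @param termini 2 x 2 matrix: the innermost `(col, row)` of each side's
#'   reference curve (left row first).
#' @return An object of class `boundary_annotation`.
#' @export
boundary_annotation <- function(inner_boundary, outer_boundary,
                                reference_points, termini) {
  inner <- check_x_monotone(as_polyline(inner_boundary, "inner_boundary"),
                            "inner_boundary")
  outer <- check_x_monotone(as_polyline(outer_boundary, "outer_boundary"),
                            "outer_boundary")
  if (nrow(inner) < 3L || nrow(outer) < 3L) {
    pct_stop("pctopo_annotation_error",
             "boundary polylines need at least 3 vertices")
  }
  if (!is.list(reference_points) || length(reference_points) != 2L) {
    pct_stop("pctopo_annotation_error",
             "reference_points must be a list of two polylines (left, right)")
  }
  refs <- lapply(seq_along(reference_points), function(i) {
    check_x_monotone(
      as_polyline(reference_points[[i]], sprintf("reference_points[[%d]]", i)),
      sprintf("reference_points[[%d]]", i))
  })
  # order sides left/right by lateral position
  if (mean(refs[[1L]][, 1L]) > mean(refs[[2L]][, 1L])) refs <- rev(refs)
  term <- as_polyline(termini, "termini")
  if (nrow(term) != 2L) {
    pct_stop("pctopo_annotation_error",
             "exactly two termini are required, one per side")
  }
  if (term[1L, 1L] > term[2L, 1L]) term <- term[2:1, , drop = FALSE]
  # inner boundary above outer over the common lateral span
  span <- c(max(min(inner[, 1L]), min(outer[, 1L])),
            min(max(inner[, 1L]), max(outer[, 1L])))
  if (span[1L] < span[2L]) {
    xs <- seq(span[1L], span[2L], length.out = 64L)
    yi <- stats::approx(inner[, 1L], inner[, 2L], xout = xs)$y
    yo <- stats::approx(outer[, 1L], outer[, 2L], xout = xs)$y
    if (any(yi >= yo)) {
      pct_stop("pctopo_annotation_error",
               "inner boundary must lie above the outer boundary")
    }
  }
  structure(list(
    inner_boundary = inner, outer_boundary = outer,
    reference_points = refs, termini = term
  ), class = "boundary_annotation")
}

# Convert an annotation from pixel to physical um coordinates.
annotation_to_um <- function(annotation, scan) {
  sc <- function(p) cbind(x = p[, 1L] * scan$lateral_scale_um,
                          y = p[, 2L] * scan$axial_scale_um)
  structure(list(
    inner_boundary = sc(annotation$inner_boundary),
    outer_boundary = sc(annotation$outer_boundary),
    reference_points = lapply(annotation$reference_points, sc),
    termini = sc(annotation$termini)
  ), class = "boundary_annotation_um")
}

SIDEcar_required <- c("image", "lateral_scale_um", "axial_scale_um",
                      "scan_width_mm", "direction_axis_deg", "eye",
                      "signal_strength")

read_gray_image <- function(path) {
  if (!file.exists(path)) {
    pct_stop("pctopo_io_error", "image file not found: %s", path)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    pct_stop("pctopo_format_error", "unsupported image format: .%s", ext))
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3L]
    same <- all(vapply(seq_len(ch)[-1L],
                       function(k) isTRUE(all.equal(img[, , 1L], img[, , k])),
                       logical(1L)))
    if (!same) {
      pct_stop("pctopo_format_error",
               "image is not grayscale: %d distinct channels", ch)
    }
    img <- img[, , 1L]
  }
  pmin(pmax(img, 0), 1)
}

#' Read a B-scan image with its JSON sidecar
#'
#' @param image_path Grayscale single-channel TIFF or PNG.
#' @param meta_path JSON sidecar with calibration/acquisition metadata and
#'   (optionally) the boundary annotation.
#' @return A `bscan`; if the sidecar contains annotation polylines they
#'   are attached as `attr(scan, "annotation")`.
#' @export
read_bscan <- function(image_path, meta_path) {
  if (!file.exists(meta_path)) {
    pct_stop("pctopo_io_error", "metadata file not found: %s", meta_path)
  }
  meta <- jsonlite::fromJSON(meta_path, simplifyMatrix = TRUE)
  missing <- setdiff(SIDEcar_required, names(meta))
  if (length(missing)) {
    pct_stop("pctopo_schema_error",
             "sidecar is missing required field(s): %s",
             paste(missing, collapse = ", "))
  }
  img <- read_gray_image(image_path)
  scan <- bscan(img,
                lateral_scale_um = meta$lateral_scale_um,
                axial_scale_um = meta$axial_scale_um,
                scan_width_mm = meta$scan_width_mm,
                direction_axis_deg = meta$direction_axis_deg,
                eye = meta$eye,
                signal_strength = meta$signal_strength)
  ann_keys <- c("inner_boundary", "outer_boundary", "reference_points",
                "termini")
  if (all(ann_keys %in% names(meta))) {
    attr(scan, "annotation") <- boundary_annotation(
      meta$inner_boundary, meta$outer_boundary,
      if (is.list(meta$reference_points)) meta$reference_points
      else list(meta$reference_points),
      meta$termini)
  }
  scan
}

#' Write a B-scan and sidecar to disk
#'
#' @param scan A `bscan`.
#' @param image_path Output TIFF (`.tif`/`.tiff`) or PNG path.
#' @param meta_path Output JSON sidecar path.
#' @param annotation Optional `boundary_annotation` to embed in the sidecar.
#' @return Invisibly, `image_path`.
#' @export
write_bscan <- function(scan, image_path, meta_path, annotation = NULL) {
  stopifnot(inherits(scan, "bscan"))
  ext <- tolower(tools::file_ext(image_path))
  ok <- switch(ext,
    tif = , tiff = tiff::writeTIFF(scan$pixels, image_path,
                                   bits.per.sample = 16L),
    png = png::writePNG(scan$pixels, image_path),
    pct_stop("pctopo_format_error", "unsupported image format: .%s", ext))
  meta <- list(
    image = basename(image_path),
    lateral_scale_um = scan$lateral_scale_um,
    axial_scale_um = scan$axial_scale_um,
    scan_width_mm = scan$scan_width_mm,
    direction_axis_deg = scan$direction_axis_deg,
    eye = scan$eye,
    signal_strength = scan$signal_strength)
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "boundary_annotation"))
    meta$inner_boundary <- unname(annotation$inner_boundary)
    meta$outer_boundary <- unname(annotation$outer_boundary)
    meta$reference_points <- lapply(annotation$reference_points, unname)
    meta$termini <- unname(annotation$termini)
  }
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}

#' Validate a four-direction scan set
#'
#' Accepts exactly one scan per cross-line axis (0, 45, 90, 135 degrees),
#' all from the same eye.  Scans with signal strength below 7 are flagged
#' (`low_signal = TRUE`) but kept; the exclusion rule is applied at cohort
#' assembly, not here.
#'
#' @param scans List of four `bscan` objects in any order.
#' @param subject_id,session_id Optional identifiers carried through.
#' @return An object of class `scan_set` with scans ordered by axis.
#' @export
validate_scan_set <- function(scans, subject_id = NA_character_,
                              session_id = NA_character_) {
  if (!length(scans)) pct_stop("pctopo_validation_error", "empty scan list")
  if (!all(vapply(scans, inherits, logical(1L), "bscan"))) {
    pct_stop("pctopo_validation_error", "all elements must be bscan objects")
  }
  axes <- vapply(scans, function(s) s$direction_axis_deg, numeric(1L))
  missing <- setdiff(VALID_AXES, axes)
  dup <- unique(axes[duplicated(axes)])
  if (length(missing) || length(dup)) {
    pct_stop("pctopo_validation_error",
             "scan set needs one scan per axis {0,45,90,135}; missing: {%s}; duplicated: {%s}",
             paste(missing, collapse = ","), paste(dup, collapse = ","))
  }
  eyes <- unique(vapply(scans, function(s) s$eye, character(1L)))
  if (length(eyes) != 1L) {
    pct_stop("pctopo_validation_error",
             "mixed laterality in scan set: %s", paste(eyes, collapse = ", "))
  }
  scans <- scans[order(axes)]
  scans <- lapply(scans, function(s) {
    s$low_signal <- s$signal_strength < 7L
    s
  })
  structure(list(scans = scans, eye = eyes, subject_id = subject_id,
                 session_id = session_id),
            class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  nlow <- sum(vapply(x$scans, function(s) isTRUE(s$low_signal), logical(1L)))
  cat(sprintf("<scan_set> %s, 4 axes, %d low-signal scan(s)\n", x$eye, nlow))
  invisible(x)
}

#' Write directional thickness profiles to CSV
#'
#' Long format with header `direction_deg, distance_mm, thickness_um,
#' valid`; distances in mm to 6 decimals, thickness in um to 3 decimals.
#'
#' @param profiles A `thickness_profile` or list of them.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(profiles, path) {
  if (inherits(profiles, "thickness_profile")) profiles <- list(profiles)
  if (!length(profiles) ||
      !all(vapply(profiles, inherits, logical(1L), "thickness_profile")) ||
      !sum(vapply(profiles, function(p) nrow(p$samples), integer(1L)))) {
    pct_stop("pctopo_io_error", "no profile samples to write; file not created")
  }
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(direction_deg = p$direction,
               distance_mm = round(p$samples$distance_mm, 6L),
               thickness_um = round(p$samples$thickness_um, 3L),
               valid = as.integer(p$samples$valid))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read profiles written by [write_profile_csv()]
#'
#' @param path CSV path.
#' @return List of `thickness_profile` objects, one per direction.
#' @export
read_profile_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("direction_deg", "distance_mm", "thickness_um", "valid")
  if (!all(need %in% names(d))) {
    pct_stop("pctopo_schema_error", "profile CSV must have columns %s",
             paste(need, collapse = ", "))
  }
  lapply(split(d, d$direction_deg), function(g) {
    thickness_profile(direction = g$direction_deg[1L],
                      distance_mm = g$distance_mm,
                      thickness_um = g$thickness_um,
                      valid = as.logical(g$valid))
  })
}

#' Write a topography map as long-format CSV
#'
#' Columns `angle_deg, radius_mm, thickness_um`; map metadata (laterality,
#' disc radius, extent) is stored in `#`-prefixed header comments so the
#' file round-trips through [read_topography()].
#'
#' @param map A `topography_map`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_topography <- function(map, path) {
  stopifnot(inherits(map, "topography_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# laterality: %s", map$laterality),
    sprintf("# disc_radius_mm: %.6f", map$disc_radius_mm),
    sprintf("# extent_mm: %.6f", map$extent_mm)), con)
  g <- expand.grid(radius_mm = map$radii, angle_deg = map$angles)
  d <- data.frame(angle_deg = g$angle_deg,
                  radius_mm = round(g$radius_mm, 6L),
                  thickness_um = round(as.vector(map$values), 3L))
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a topography map written by [write_topography()]
#' @param path CSV path.
#' @return A `topography_map`.
#' @export
read_topography <- function(path) {
  hdr <- readLines(path, n = 3L)
  field <- function(key) sub(sprintf("^# %s: ", key), "", hdr[grepl(key, hdr)])
  d <- utils::read.csv(path, comment.char = "#")
  angles <- sort(unique(d$angle_deg))
  radii <- sort(unique(d$radius_mm))
  vals <- matrix(d$thickness_um[order(d$angle_deg, d$radius_mm)],
                 nrow = length(radii), ncol = length(angles))
  topography_map(angles = angles, radii = radii, values = vals,
                 laterality = field("laterality"),
                 disc_radius_mm = as.numeric(field("disc_radius_mm")))
}

#' Read/write a cohort table
#'
#' One row per subject with the column layout produced by
#' [generate_cohort()]; see [cohort_columns()].
#'
#' @param path CSV path.
#' @return A data.frame of class `pct_cohort`.
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_columns(), names(d))
  if (length(missing)) {
    pct_stop("pctopo_schema_error", "cohort CSV is missing column(s): %s",
             paste(missing, collapse = ", "))
  }
  d$autoimmune_flag <- as.logical(d$autoimmune_flag)
  d$brain_mri_flag <- as.logical(d$brain_mri_flag)
  class(d) <- c("pct_cohort", "data.frame")
  d
}

#' @rdname read_cohort_csv
#' @param cohort Cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
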