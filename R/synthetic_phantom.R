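# Phantom peripapillary B-scans with exact ground truth.
#
# Layer geometry is defined analytically in physical coordinates: the
# choroid inner boundary (Bruch's membrane) is a polynomial in lateral
# position, the outer boundary is its offset along the local normal by
# the ground-truth thickness function, and the reference curve is the
# inner boundary shifted toward the vitreous.  The rendered image is
# cosmetic; the exported annotation polylines are exact, so the phantom
# verifies the measurement geometry, not a segmentation algorithm.

#' Specify a phantom B-scan
#'
#' Curve coefficients are ascending polynomial coefficients in um as a
#' function of lateral position in mm measured from the scan center.
#'
#' @param scan_width_mm Scan line length (default 8).
#' @param lateral_scale_um,axial_scale_um Pixel scales (default 12.5 and
#'   4 um/px).
#' @param depth_mm Imaged depth (default 1.92 mm).
#' @param inner_coef Choroid inner boundary polynomial (um vs mm from
#'   center); default a gentle parabola `900 + 25 x^2`.
#' @param thickness Ground-truth perpendicular thickness function: a list
#'   with `type` in `"constant"`, `"linear"`, `"harmonic"`; `base_um`;
#'   `slope_um_per_mm` (linear); `amplitude_um`, `period_mm`, `phase_deg`
#'   (harmonic).
#' @param disc_gap_mm Disc half-width used for image rendering (default
#'   0.8).
#' @param terminus_offset_mm Lateral distance of each Bruch's terminus
#'   from the scan center, `c(left, right)`; the defaults (0.85, 0.90 mm)
#'   with a 0.1 mm edge margin give per-side measurable spans of 3.05 and
#'   3.00 mm, inside the 2.83–3.18 mm range seen in practice.
#' @param edge_margin_mm Unannotated margin at each lateral edge (0.1).
#' @param reference_offset_um Vitreous-ward offset of the reference curve
#'   from the inner boundary (default 30 um).
#' @param swelling_factor Multiplies the rendered retina band height
#'   (default 1; around 1.36 emulates a swollen disc).
#' @param speckle_contrast,additive_sd Rendering noise (defaults 0).
#' @param direction_axis_deg,eye,signal_strength Scan metadata.
#' @param seed RNG seed for the rendered noise.
#' @return A validated `phantom_spec`.
#' @export
phantom_spec <- function(scan_width_mm = 8,
                         lateral_scale_um = 12.5,
                         axial_scale_um = 4,
                         depth_mm = 1.92,
                         inner_coef = c(900, 0, 25),
                         thickness = list(type = "constant", base_um = 200),
                         disc_gap_mm = 0.8,
                         terminus_offset_mm = c(0.85, 0.90),
                         edge_margin_mm = 0.1,
                         reference_offset_um = 30,
                         swelling_factor = 1,
                         speckle_contrast = 0,
                         additive_sd = 0,
                         direction_axis_deg = 0,
                         eye = "OD",
                         signal_strength = 10L,
                         seed = 1L) {
  spec <- list(scan_width_mm = scan_width_mm,
               lateral_scale_um = lateral_scale_um,
               axial_scale_um = axial_scale_um,
               depth_mm = depth_mm,
               inner_coef = inner_coef,
               thickness = thickness,
               disc_gap_mm = disc_gap_mm,
               terminus_offset_mm = terminus_offset_mm,
               edge_margin_mm = edge_margin_mm,
               reference_offset_um = reference_offset_um,
               swelling_factor = swelling_factor,
               speckle_contrast = speckle_contrast,
               additive_sd = additive_sd,
               direction_axis_deg = direction_axis_deg,
               eye = eye,
               signal_strength = signal_strength,
               seed = seed)
  class(spec) <- "phantom_spec"
  xs <- seq(-scan_width_mm / 2, scan_width_mm / 2, length.out = 512L)
  if (any(phantom_thickness(spec, xs * 1000 + scan_width_mm * 500) <= 0)) {
    pct_stop("pctopo_spec_error",
             "thickness function must be positive across the scan")
  }
  if (any(terminus_offset_mm <= 0) ||
      any(terminus_offset_mm >= scan_width_mm / 2 - edge_margin_mm)) {
    pct_stop("pctopo_spec_error", "terminus offsets outside the scan")
  }
  spec
}

# Evaluate the ground-truth perpendicular thickness (um) at lateral
# position x_um measured from the image-left edge.
phantom_thickness <- function(spec, x_um) {
  xm <- x_um / 1000 - spec$scan_width_mm / 2
  th <- spec$thickness
  switch(th$type,
    constant = rep(th$base_um, length(xm)),
    linear = th$base_um + th$slope_um_per_mm * xm,
    harmonic = th$base_um + th$amplitude_um *
      sin(2 * pi * xm / th$period_mm + (th$phase_deg %||% 0) * pi / 180),
    pct_stop("pctopo_spec_error", "unknown thickness type '%s'", th$type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

phantom_inner <- function(spec, x_um, deriv = 0L) {
  xm <- x_um / 1000 - spec$scan_width_mm / 2
  cf <- spec$inner_coef
  d <- length(cf) - 1L
  if (deriv == 0L) {
    y <- rep(cf[d + 1L], length(xm))
    if (d >= 1L) for (k in d:1L) y <- y * xm + cf[k]
    y
  } else {
    if (d == 0L) return(rep(0, length(xm)))
    b <- cf[-1L] * seq_len(d)
    y <- rep(b[d], length(xm))
    if (d >= 2L) for (k in (d - 1L):1L) y <- y * xm + b[k]
    y / 1000                     # um per um
  }
}

#' Generate a phantom B-scan with exact annotations and oracle
#'
#' Renders a layered grayscale image (dark vitreous, bright retina band
#' whose height scales with the swelling factor, textured choroid, dim
#' sclera, disc gap) and returns exact boundary annotations plus a
#' callable ground-truth oracle.  Deterministic for a fixed seed; noise
#' affects only the rendered pixels, never the annotations.
#'
#' @param spec A [phantom_spec()].
#' @return List with `scan` (`bscan`), `annotation`
#'   (`boundary_annotation`, pixel coordinates), `oracle`
#'   (function of lateral position in um from the image-left edge,
#'   returning perpendicular thickness in um) and `spec`.
#' @export
generate_phantom_scan <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  ls <- spec$lateral_scale_um
  as_ <- spec$axial_scale_um
  width_um <- spec$scan_width_mm * 1000
  ncol_px <- floor(width_um / ls) + 1L
  nrow_px <- floor(spec$depth_mm * 1000 / as_) + 1L
  cx <- width_um / 2

  x_cols <- (seq_len(ncol_px) - 1L) * ls          # um, 0-based columns
  y_in <- phantom_inner(spec, x_cols)
  slope <- phantom_inner(spec, x_cols, deriv = 1L)
  nrm <- sqrt(1 + slope^2)
  nx <- -slope / nrm
  ny <- 1 / nrm
  t_true <- phantom_thickness(spec, x_cols)
  # outer boundary: normal offset of the inner boundary
  xo <- x_cols + t_true * nx
  yo <- y_in + t_true * ny
  retina_h <- 250 * spec$swelling_factor          # rendered band height, um
  y_surf <- y_in - retina_h

  img <- matrix(0.05, nrow_px, ncol_px)           # vitreous
  rows_um <- (seq_len(nrow_px) - 1L) * as_
  in_gap <- abs(x_cols - cx) < spec$disc_gap_mm * 1000
  y_out_cols <- stats::approx(xo, yo, xout = x_cols, rule = 2L)$y
  for (j in seq_len(ncol_px)) {
    if (in_gap[j]) {
      img[rows_um >= y_surf[j], j] <- 0.62        # disc tissue
      next
    }
    img[rows_um >= y_surf[j] & rows_um < y_in[j], j] <- 0.75
    img[rows_um >= y_in[j] & rows_um < y_out_cols[j], j] <- 0.45
    img[rows_um >= y_out_cols[j], j] <- 0.18
  }
  if (spec$speckle_contrast > 0 || spec$additive_sd > 0) {
    img <- with_seed(spec$seed, {
      out <- img
      if (spec$speckle_contrast > 0) {
        out <- out * (1 + spec$speckle_contrast *
                        (matrix(stats::runif(length(out)), nrow(out)) - 0.5))
      }
      if (spec$additive_sd > 0) {
        out <- out + matrix(stats::rnorm(length(out), 0, spec$additive_sd),
                            nrow(out))
      }
      out
    })
  }
  # quantize to the 16-bit grid used on disk so write/read round-trips
  # are bit-exact
  img <- round(pmin(pmax(img, 0), 1) * 65535) / 65535

  scan <- bscan(img, lateral_scale_um = ls, axial_scale_um = as_,
                scan_width_mm = spec$scan_width_mm,
                direction_axis_deg = spec$direction_axis_deg,
                eye = spec$eye, signal_strength = spec$signal_strength)

  # exact annotations in pixel coordinates (sub-pixel values allowed)
  margin <- spec$edge_margin_mm * 1000
  span <- x_cols >= margin & x_cols <= width_um - margin
  inner_px <- cbind(x_cols[span] / ls, y_in[span] / as_)
  ok_o <- xo >= margin & xo <= width_um - margin
  outer_px <- cbind(xo[ok_o] / ls, yo[ok_o] / as_)
  d <- spec$reference_offset_um
  y_ref <- y_in - d
  tl <- cx - spec$terminus_offset_mm[1L] * 1000
  tr <- cx + spec$terminus_offset_mm[2L] * 1000
  left <- x_cols >= margin & x_cols <= tl
  right <- x_cols >= tr & x_cols <= width_um - margin
  ref_left <- cbind(x_cols[left] / ls, y_ref[left] / as_)
  ref_right <- cbind(x_cols[right] / ls, y_ref[right] / as_)
  term_y <- (phantom_inner(spec, c(tl, tr)) - d) / as_
  termini <- rbind(c(tl / ls, term_y[1L]), c(tr / ls, term_y[2L]))
  annotation <- boundary_annotation(inner_px, outer_px,
                                    list(ref_left, ref_right), termini)
  list(scan = scan,
       annotation = annotation,
       oracle = function(x_um) phantom_thickness(spec, x_um),
       spec = spec)
}

#' Write a phantom bundle to a directory
#'
#' Creates `image.tiff`, `annotation.json` (sidecar with metadata and
#' annotation) and `truth.csv` (lateral position vs ground-truth
#' thickness).
#'
#' @param phantom Result of [generate_phantom_scan()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_phantom_bundle <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bscan(phantom$scan,
              file.path(dir, "image.tiff"),
              file.path(dir, "annotation.json"),
              annotation = phantom$annotation)
  xs <- seq(0, phantom$spec$scan_width_mm * 1000, by = 10)
  utils::write.csv(
    data.frame(x_um = xs, thickness_um = round(phantom$oracle(xs), 4L)),
    file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Generate a four-scan phantom set for one eye
#'
#' One phantom per cross-line axis; per-axis thickness functions may be
#' supplied to create angular structure.
#'
#' @param base_spec Template [phantom_spec()].
#' @param thickness_by_axis Optional named list (`"0"`, `"45"`, `"90"`,
#'   `"135"`) of thickness function lists overriding the template's.
#' @return List of four phantom bundles (as from
#'   [generate_phantom_scan()]), ordered by axis.
#' @export
generate_phantom_set <- function(base_spec = phantom_spec(),
                                 thickness_by_axis = NULL) {
  lapply(VALID_AXES, function(ax) {
    sp <- base_spec
    sp$direction_axis_deg <- ax
    sp$seed <- base_spec$seed + ax
    th <- thickness_by_axis[[as.character(ax)]]
    if (!is.null(th)) sp$thickness <- th
    generate_phantom_scan(sp)
  })
}
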