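# Geometry engine: reference-curve smoothing, perpendicular sampling,
# thickness measurement, disc-center localisation.
#
# All geometry is done in physical micrometre coordinates (both pixel
# scales applied first) so that "perpendicular" means physically
# perpendicular even on anisotropic pixel grids.

#' Fit a smoothing polynomial to a hand-drawn reference curve
#'
#' Removes hand-tremor artifacts by least-squares fitting a polynomial of
#' the given degree to the reference polyline.  The fit is performed in a
#' centred/scaled abscissa for numerical stability; raw-basis coefficients
#' are available through [coef.smoothed_curve()].
#'
#' @param points Polyline (n x 2 matrix) of `(x, y)` positions in um,
#'   x-monotone.
#' @param degree Polynomial order, 1..8 (default 4).
#' @return A `smoothed_curve` with fields `degree`, `domain` (um) and
#'   `residual_rms_um` for QC.
#' @export
smooth_reference_curve <- function(points, degree = 4L) {
  p <- as_polyline(points, "reference curve")
  p <- check_x_monotone(p, "reference curve")
  degree <- as.integer(degree)
  if (degree < 1L || degree > 8L) {
    pct_stop("pctopo_spec_error", "degree must be between 1 and 8")
  }
  if (nrow(p) < degree + 1L) {
    pct_stop("pctopo_fit_error",
             "need at least %d points for a degree-%d fit, got %d",
             degree + 1L, degree, nrow(p))
  }
  ctr <- mean(range(p[, 1L]))
  scl <- max(diff(range(p[, 1L])) / 2, 1)
  u <- (p[, 1L] - ctr) / scl
  X <- outer(u, 0:degree, `^`)
  fit <- stats::lm.fit(X, p[, 2L])
  res <- fit$residuals
  structure(list(
    coef_scaled = unname(fit$coefficients),
    center = ctr, scale = scl, degree = degree,
    domain = range(p[, 1L]),
    residual_rms_um = sqrt(mean(res^2))
  ), class = "smoothed_curve")
}

#' @export
print.smoothed_curve <- function(x, ...) {
  cat(sprintf("<smoothed_curve> degree %d on [%.1f, %.1f] um, residual RMS %.3g um\n",
              x$degree, x$domain[1L], x$domain[2L], x$residual_rms_um))
  invisible(x)
}

#' Raw-basis polynomial coefficients of a smoothed curve
#'
#' @param object A `smoothed_curve`.
#' @param ... Unused.
#' @return Numeric vector of coefficients in ascending powers of x (um).
#' @export
coef.smoothed_curve <- function(object, ...) {
  # expand p(u), u = (x - c)/s, into powers of x
  a <- object$coef_scaled
  d <- object$degree
  out <- numeric(d + 1L)
  for (k in 0:d) {
    # a_k * ((x - c)/s)^k = a_k / s^k * sum_j C(k,j) x^j (-c)^(k-j)
    j <- 0:k
    out[j + 1L] <- out[j + 1L] +
      a[k + 1L] / object$scale^k * choose(k, j) * (-object$center)^(k - j)
  }
  out
}

# Evaluate the curve / its derivative at x (um).
curve_eval <- function(curve, x, deriv = 0L) {
  u <- (x - curve$center) / curve$scale
  a <- curve$coef_scaled
  d <- curve$degree
  if (deriv == 0L) {
    y <- rep(a[d + 1L], length(x))
    if (d >= 1L) for (k in (d - 1L):0L) y <- y * u + a[k + 1L]
    y
  } else {
    b <- a[-1L] * seq_len(d)     # derivative in u
    y <- rep(b[d], length(x))
    if (d >= 2L) for (k in (d - 1L):1L) y <- y * u + b[k]
    y / curve$scale
  }
}

#' Place perpendicular auxiliary lines along a smoothed curve
#'
#' Anchors are spaced at a fixed arc-length interval along the curve; at
#' each anchor the unit normal points toward increasing depth (the outer
#' choroid), i.e. has a positive axial component.
#'
#' @param curve A `smoothed_curve`.
#' @param interval_um Arc-length spacing in um (default 1).
#' @param from_um,to_um Lateral sub-interval to sample (defaults to the
#'   curve domain).
#' @return Data.frame with columns `x, y` (anchor, um), `nx, ny` (unit
#'   normal) and `arc_um` (arc length from `from_um`).
#' @export
sample_perpendiculars <- function(curve, interval_um = 1,
                                  from_um = curve$domain[1L],
                                  to_um = curve$domain[2L]) {
  stopifnot(inherits(curve, "smoothed_curve"))
  if (!is_number(interval_um) || interval_um <= 0) {
    pct_stop("pctopo_spec_error", "interval must be > 0")
  }
  if (from_um >= to_um) {
    pct_stop("pctopo_spec_error", "empty sampling interval [%g, %g]",
             from_um, to_um)
  }
  # cumulative arc length on a fine grid, then inverse interpolation
  step <- min(interval_um / 4, (to_um - from_um) / 64)
  xg <- seq(from_um, to_um, by = step)
  if (xg[length(xg)] < to_um) xg <- c(xg, to_um)
  dy <- curve_eval(curve, xg, deriv = 1L)
  seg <- sqrt(1 + ((dy[-1L] + dy[-length(dy)]) / 2)^2) * diff(xg)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (interval_um > total) {
    pct_stop("pctopo_spec_error",
             "interval (%g um) exceeds curve arc length (%g um)",
             interval_um, total)
  }
  targets <- seq(0, total, by = interval_um)
  xa <- stats::approx(s, xg, xout = targets, ties = "ordered")$y
  ya <- curve_eval(curve, xa)
  d1 <- curve_eval(curve, xa, deriv = 1L)
  nrm <- sqrt(1 + d1^2)
  data.frame(x = xa, y = ya, nx = -d1 / nrm, ny = 1 / nrm, arc_um = targets)
}

# Signed distance along the line (x0,y0) + t*(nx,ny) to the nearest
# intersection with an x-monotone polyline (vertices vx, vy ascending in
# x).  Returns NA when the line misses the polyline.
ray_polyline_t <- function(x0, y0, nx, ny, vx, vy) {
  if (abs(nx) < 1e-12) {
    if (x0 < vx[1L] || x0 > vx[length(vx)]) return(NA_real_)
    yb <- stats::approx(vx, vy, xout = x0, ties = "ordered")$y
    return((yb - y0) / ny)
  }
  tv <- (vx - x0) / nx                      # line parameter at each vertex x
  g <- vy - (y0 + tv * ny)                  # boundary minus line, at vertices
  sgn <- g[-1L] * g[-length(g)]
  hit <- which(sgn <= 0)
  if (!length(hit)) return(NA_real_)
  # linear interpolation inside each bracketing segment (g is piecewise
  # linear in t), pick intersection nearest the anchor
  t1 <- tv[hit]; t2 <- tv[hit + 1L]
  g1 <- g[hit];  g2 <- g[hit + 1L]
  tt <- ifelse(g1 == g2, t1, t1 - g1 * (t2 - t1) / (g2 - g1))
  tt[which.min(abs(tt))]
}

#' Measure choroid thickness along perpendicular auxiliary lines
#'
#' For each perpendicular, thickness is the Euclidean distance between its
#' intersections with the inner and outer choroid boundary polylines
#' (linearly interpolated between vertices), in um.  Perpendiculars that
#' miss either boundary yield invalid samples — values are never
#' fabricated.  When a boundary is crossed more than once the intersection
#' nearest the anchor is used.
#'
#' @param curve A `smoothed_curve` (reference curve, um coordinates).
#' @param annotation A `boundary_annotation` (pixel coordinates) or a
#'   `boundary_annotation_um`.
#' @param scan The `bscan` supplying pixel scales (ignored when
#'   `annotation` is already in um).
#' @param interval_um Arc-length sampling interval (default 1 um).
#' @param from_um,to_um Lateral sub-interval to measure.
#' @return Data.frame: anchor `x, y` (um), `arc_um`, `thickness_um`,
#'   `valid`.
#' @export
measure_thickness <- function(curve, annotation, scan = NULL,
                              interval_um = 1,
                              from_um = curve$domain[1L],
                              to_um = curve$domain[2L]) {
  ann <- if (inherits(annotation, "boundary_annotation_um")) annotation
  else {
    if (is.null(scan)) {
      pct_stop("pctopo_spec_error",
               "scan is required to convert a pixel annotation to um")
    }
    annotation_to_um(annotation, scan)
  }
  per <- sample_perpendiculars(curve, interval_um, from_um, to_um)
  ivx <- ann$inner_boundary[, 1L]; ivy <- ann$inner_boundary[, 2L]
  ovx <- ann$outer_boundary[, 1L]; ovy <- ann$outer_boundary[, 2L]
  n <- nrow(per)
  thick <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ti <- ray_polyline_t(per$x[i], per$y[i], per$nx[i], per$ny[i], ivx, ivy)
    if (is.na(ti)) next
    to <- ray_polyline_t(per$x[i], per$y[i], per$nx[i], per$ny[i], ovx, ovy)
    if (is.na(to)) next
    thick[i] <- abs(to - ti)
  }
  if (!any(!is.na(thick))) {
    pct_stop("pctopo_measure_error",
             "no perpendicular intersects both choroid boundaries")
  }
  data.frame(x = per$x, y = per$y, arc_um = per$arc_um,
             thickness_um = thick, valid = !is.na(thick))
}

#' Locate the disc center from the Bruch's membrane termini
#'
#' The disc center is the midpoint of the two termini (the innermost ends
#' of the two reference curves); the disc diameter is their separation.
#'
#' @param left_terminus,right_terminus `(x, y)` in um.
#' @param laterality `"OD"` or `"OS"`.
#' @return A `disc_geometry` with `center_um` and `diameter_mm`.
#' @export
locate_disc_center <- function(left_terminus, right_terminus,
                               laterality = "OD") {
  lt <- as.numeric(left_terminus); rt <- as.numeric(right_terminus)
  if (length(lt) != 2L || length(rt) != 2L || anyNA(c(lt, rt))) {
    pct_stop("pctopo_spec_error", "termini must be finite (x, y) pairs")
  }
  d <- sqrt(sum((lt - rt)^2))
  if (d == 0) {
    pct_stop("pctopo_annotation_error", "termini coincide; disc has no extent")
  }
  structure(list(center_um = (lt + rt) / 2, diameter_mm = d / 1000,
                 laterality = laterality),
            class = "disc_geometry")
}

#' Compare lesion and fellow disc diameters
#'
#' A ratio outside the configurable band signals possible disc-margin
#' mis-annotation (swollen discs make the margin hard to judge).
#'
#' @param lesion,fellow `disc_geometry` objects (or diameters in mm).
#' @param band Acceptable lesion/fellow ratio band (default 0.9–1.1).
#' @return List with `ratio` and logical `flag`.
#' @export
compare_disc_diameters <- function(lesion, fellow, band = c(0.9, 1.1)) {
  dl <- if (inherits(lesion, "disc_geometry")) lesion$diameter_mm else lesion
  df <- if (inherits(fellow, "disc_geometry")) fellow$diameter_mm else fellow
  if (!is_number(dl) || !is_number(df) || dl <= 0 || df <= 0) {
    pct_stop("pctopo_spec_error", "disc diameters must be positive")
  }
  r <- dl / df
  list(ratio = r, flag = r < band[1L] || r > band[2L])
}

#' Construct a directional thickness profile
#'
#' @param direction Direction in degrees (0, 45, ..., 315).
#' @param distance_mm Distances from the disc margin, strictly increasing
#'   from 0.
#' @param thickness_um Thickness samples (um); `NA` where invalid.
#' @param valid Logical validity flags.
#' @param interval_um Sampling interval used (um).
#' @return A `thickness_profile`.
#' @export
thickness_profile <- function(direction, distance_mm, thickness_um,
                              valid = !is.na(thickness_um),
                              interval_um = NA_real_) {
  if (length(distance_mm) != length(thickness_um)) {
    pct_stop("pctopo_spec_error", "distance and thickness lengths differ")
  }
  if (length(distance_mm) && (any(diff(distance_mm) <= 0) ||
                              distance_mm[1L] < 0)) {
    pct_stop("pctopo_spec_error",
             "profile distances must strictly increase from 0")
  }
  if (any(thickness_um[valid] < 0, na.rm = TRUE)) {
    pct_stop("pctopo_spec_error", "valid thickness must be >= 0")
  }
  structure(list(
    direction = as.numeric(direction),
    samples = data.frame(distance_mm = as.numeric(distance_mm),
                         thickness_um = as.numeric(thickness_um),
                         valid = as.logical(valid)),
    extent_mm = if (length(distance_mm)) max(distance_mm) else 0,
    interval_um = interval_um
  ), class = "thickness_profile")
}

#' @export
print.thickness_profile <- function(x, ...) {
  cat(sprintf("<thickness_profile> %g deg, %d samples to %.3f mm, %.1f%% valid\n",
              x$direction, nrow(x$samples), x$extent_mm,
              100 * mean(x$samples$valid)))
  invisible(x)
}

#' Build the two directional profiles of one cross-line scan
#'
#' Each B-scan crosses the disc and contributes two of the eight
#' directions: the side at increasing lateral position is assigned the
#' scan axis, the opposite side axis + 180 degrees.  Each side's reference
#' polyline is smoothed, perpendiculars are sampled outward from that
#' side's Bruch's terminus, and samples are indexed by distance from the
#' disc margin.
#'
#' A profile with more than `max_invalid_frac` invalid samples is rejected;
#' if only one side is measurable a single profile is returned with a
#' warning.
#'
#' @param scan A `bscan`.
#' @param annotation Its `boundary_annotation` (pixel coordinates).
#' @param disc Optional `disc_geometry`; computed from the termini when
#'   missing.
#' @param interval_um Sampling interval (default 1 um).
#' @param degree Smoothing polynomial degree (default 4).
#' @param max_invalid_frac Maximum tolerated invalid fraction (default 0.2).
#' @return List of `thickness_profile` objects (normally two).
#' @export
build_direction_profiles <- function(scan, annotation, disc = NULL,
                                     interval_um = 1, degree = 4L,
                                     max_invalid_frac = 0.2) {
  ann <- annotation_to_um(annotation, scan)
  if (is.null(disc)) {
    disc <- locate_disc_center(ann$termini[1L, ], ann$termini[2L, ],
                               laterality = scan$eye)
  }
  sides <- list(
    list(ref = ann$reference_points[[1L]], terminus = ann$termini[1L, ],
         direction = (scan$direction_axis_deg + 180) %% 360, leftward = TRUE),
    list(ref = ann$reference_points[[2L]], terminus = ann$termini[2L, ],
         direction = scan$direction_axis_deg, leftward = FALSE))
  out <- list()
  for (sd in sides) {
    prof <- tryCatch({
      curve <- smooth_reference_curve(sd$ref, degree = degree)
      tx <- sd$terminus[1L]
      m <- measure_thickness(curve, ann, interval_um = interval_um,
                             from_um = if (sd$leftward) curve$domain[1L] else tx,
                             to_um = if (sd$leftward) tx else curve$domain[2L])
      if (sd$leftward) {
        # distance grows away from the terminus (rightmost anchor)
        m <- m[nrow(m):1L, ]
        m$arc_um <- max(m$arc_um) - m$arc_um
      }
      if (mean(!m$valid) > max_invalid_frac) {
        pct_stop("pctopo_measure_error",
                 "direction %g deg: %.0f%% of samples invalid (limit %.0f%%)",
                 sd$direction, 100 * mean(!m$valid), 100 * max_invalid_frac)
      }
      thickness_profile(direction = sd$direction,
                        distance_mm = m$arc_um / 1000,
                        thickness_um = m$thickness_um,
                        valid = m$valid,
                        interval_um = interval_um)
    }, pctopo_error = function(e) e)
    out <- c(out, list(prof))
  }
  errs <- vapply(out, inherits, logical(1L), "error")
  if (all(errs)) {
    pct_stop("pctopo_measure_error",
             "neither side of the %g-deg scan is measurable: %s",
             scan$direction_axis_deg, conditionMessage(out[[1L]]))
  }
  if (any(errs)) {
    warning(sprintf("one side of the %g-deg scan is unmeasurable: %s",
                    scan$direction_axis_deg,
                    conditionMessage(out[errs][[1L]])), call. = FALSE)
    out <- out[!errs]
  }
  out
}
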