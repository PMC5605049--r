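# Full-circle choroid thickness topography: trim eight directional
# profiles to a common radial extent, join them across angle with a
# periodic cubic spline, and summarise PCT / TemPCT over the annulus.
#
# Radial positions are distances from the disc margin (the Bruch's
# membrane terminus), in mm; the analysis domain is therefore an annulus
# whose inner edge is the disc margin.  Map angles are scan-axis angles
# (0 = image-right); the temporal meridian is resolved from laterality
# (OD: temporal = image-left = 180 deg; OS: temporal = 0 deg).

EIGHT_DIRECTIONS <- seq(0, 315, by = 45)

temporal_angle <- function(laterality) {
  if (identical(laterality, "OD")) 180 else 0
}

#' Trim directional profiles to a common radial extent
#'
#' Per-direction measurable lengths vary with disc size and annotation
#' span (typically 2.83–3.18 mm); topography requires a common extent,
#' 2.80 mm by default.
#'
#' @param profiles List of eight `thickness_profile`s, one per direction
#'   0, 45, ..., 315.
#' @param common_extent_mm Target radial extent (default 2.80).
#' @return List of trimmed profiles in direction order.
#' @export
trim_profiles <- function(profiles, common_extent_mm = 2.80) {
  dirs <- vapply(profiles, function(p) p$direction, numeric(1L))
  if (!setequal(dirs, EIGHT_DIRECTIONS) || length(profiles) != 8L) {
    pct_stop("pctopo_validation_error",
             "need exactly eight profiles at directions %s",
             paste(EIGHT_DIRECTIONS, collapse = ", "))
  }
  profiles <- profiles[order(dirs)]
  short <- vapply(profiles,
                  function(p) p$extent_mm < common_extent_mm, logical(1L))
  if (any(short)) {
    pct_stop("pctopo_validation_error",
             "profile extent below %.2f mm in direction(s): %s",
             common_extent_mm,
             paste(vapply(profiles[short], function(p) p$direction,
                          numeric(1L)), collapse = ", "))
  }
  lapply(profiles, function(p) {
    keep <- p$samples$distance_mm <= common_extent_mm + 1e-12
    thickness_profile(p$direction,
                      p$samples$distance_mm[keep],
                      p$samples$thickness_um[keep],
                      p$samples$valid[keep],
                      interval_um = p$interval_um)
  })
}

#' Construct a topography map object
#'
#' @param angles Angular grid in degrees, ascending, covering `[0, 360]`
#'   with the periodic duplicate at 360.
#' @param radii Radial grid in mm (distance from the disc margin).
#' @param values Thickness matrix (um), `length(radii)` x `length(angles)`.
#' @param laterality `"OD"` or `"OS"`.
#' @param disc_radius_mm Disc radius (mm), used for polar area weighting.
#' @return A `topography_map`.
#' @export
topography_map <- function(angles, radii, values, laterality = "OD",
                           disc_radius_mm = 0.85) {
  values <- as.matrix(values)
  if (nrow(values) != length(radii) || ncol(values) != length(angles)) {
    pct_stop("pctopo_spec_error", "values must be radii x angles")
  }
  if (max(abs(values[, 1L] - values[, ncol(values)]), na.rm = TRUE) > 1e-6) {
    pct_stop("pctopo_spec_error", "map is not periodic in angle")
  }
  structure(list(angles = as.numeric(angles), radii = as.numeric(radii),
                 values = values, laterality = laterality,
                 disc_radius_mm = as.numeric(disc_radius_mm),
                 extent_mm = max(radii)),
            class = "topography_map")
}

#' @export
print.topography_map <- function(x, ...) {
  cat(sprintf("<topography_map> %s, %d angles x %d radii to %.2f mm, disc radius %.2f mm\n",
              x$laterality, length(x$angles), length(x$radii), x$extent_mm,
              x$disc_radius_mm))
  invisible(x)
}

#' Interpolate eight trimmed profiles into a full-circle topography
#'
#' At each radius a periodic cubic spline is passed through the eight
#' (angle, thickness) knots; radially the measured samples are joined
#' linearly (they are already micrometre-dense, so no radial structure is
#' invented).  Invalid samples are filled radially from neighbouring valid
#' samples before splining.
#'
#' @param profiles Eight trimmed `thickness_profile`s of equal extent.
#' @param angular_resolution_deg Angular grid step (default 1 degree).
#' @param radial_resolution_mm Radial grid step (default 0.01 mm).
#' @param laterality `"OD"` or `"OS"`.
#' @param disc_radius_mm Disc radius in mm (default 0.85).
#' @return A `topography_map` that reproduces the knot values exactly.
#' @export
interpolate_full_circle <- function(profiles, angular_resolution_deg = 1,
                                    radial_resolution_mm = 0.01,
                                    laterality = "OD",
                                    disc_radius_mm = 0.85) {
  dirs <- vapply(profiles, function(p) p$direction, numeric(1L))
  if (!setequal(dirs, EIGHT_DIRECTIONS) || length(profiles) != 8L) {
    pct_stop("pctopo_validation_error",
             "full-circle interpolation needs all eight directions; no extrapolation across missing sectors")
  }
  profiles <- profiles[order(dirs)]
  extents <- vapply(profiles, function(p) p$extent_mm, numeric(1L))
  if (diff(range(extents)) > 1e-9) {
    pct_stop("pctopo_validation_error",
             "profiles must share a common extent; run trim_profiles() first")
  }
  extent <- extents[1L]
  radii <- seq(0, extent, by = radial_resolution_mm)
  # per-direction radial interpolation (linear between valid samples)
  knot <- vapply(profiles, function(p) {
    ok <- p$samples$valid & !is.na(p$samples$thickness_um)
    if (sum(ok) < 2L) {
      pct_stop("pctopo_measure_error",
               "direction %g deg has fewer than 2 valid samples", p$direction)
    }
    stats::approx(p$samples$distance_mm[ok], p$samples$thickness_um[ok],
                  xout = radii, rule = 2L, ties = "ordered")$y
  }, numeric(length(radii)))                     # radii x 8
  angles <- seq(0, 360, by = angular_resolution_deg)
  if (angles[length(angles)] != 360) angles <- c(angles, 360)
  vals <- matrix(NA_real_, length(radii), length(angles))
  for (i in seq_along(radii)) {
    sp <- stats::spline(x = c(EIGHT_DIRECTIONS, 360),
                        y = c(knot[i, ], knot[i, 1L]),
                        method = "periodic", xout = angles)
    vals[i, ] <- sp$y
  }
  # enforce exact knot pass-through against spline round-off
  ki <- match(EIGHT_DIRECTIONS, angles)
  ok <- !is.na(ki)
  vals[, ki[ok]] <- knot[, ok]
  vals[, length(angles)] <- vals[, 1L]
  topography_map(angles, radii, vals, laterality = laterality,
                 disc_radius_mm = disc_radius_mm)
}

# Bilinear map lookup at (angle_deg, radius_mm); periodic in angle.
map_lookup <- function(map, angle_deg, radius_mm) {
  a <- angle_deg %% 360
  av <- map$angles
  ai <- findInterval(a, av, rightmost.closed = TRUE)
  ai <- pmin(pmax(ai, 1L), length(av) - 1L)
  af <- (a - av[ai]) / (av[ai + 1L] - av[ai])
  rv <- map$radii
  ri <- findInterval(radius_mm, rv, rightmost.closed = TRUE)
  ri <- pmin(pmax(ri, 1L), length(rv) - 1L)
  rf <- (radius_mm - rv[ri]) / (rv[ri + 1L] - rv[ri])
  v00 <- map$values[cbind(ri, ai)]
  v01 <- map$values[cbind(ri, ai + 1L)]
  v10 <- map$values[cbind(ri + 1L, ai)]
  v11 <- map$values[cbind(ri + 1L, ai + 1L)]
  (1 - rf) * ((1 - af) * v00 + af * v01) + rf * ((1 - af) * v10 + af * v11)
}

#' Summarise a topography map into PCT and TemPCT
#'
#' The whole average (PCT) is the area-weighted mean of the thickness over
#' the annulus from the disc margin out to `stat_extent_mm`; the polar
#' area element gives each sample weight proportional to its distance from
#' the disc center (disc radius + radial distance).  TemPCT is the same
#' mean restricted to the temporal 180-degree semicircle, resolved from
#' the map's laterality.  Eight 45-degree sector means (centred on the
#' measured directions) are also returned.
#'
#' @param map A `topography_map`.
#' @param stat_extent_mm Radial span used for statistics (default 2.50).
#' @param weighted Use polar area weighting (default `TRUE`); `FALSE`
#'   gives the unweighted sample mean, for sensitivity checks.
#' @return A `pct_summary` list: `pct_avg_um`, `tem_pct_um`,
#'   `sector_means_um` (named by direction), `stat_extent_mm`.
#' @export
summarize_map <- function(map, stat_extent_mm = 2.50, weighted = TRUE) {
  stopifnot(inherits(map, "topography_map"))
  if (stat_extent_mm > map$extent_mm + 1e-9) {
    pct_stop("pctopo_spec_error",
             "stat extent %.2f mm exceeds map extent %.2f mm",
             stat_extent_mm, map$extent_mm)
  }
  # midpoint-rule quadrature cells in both angle and radius
  na <- 720L
  nr <- max(64L, length(map$radii))
  ang <- (seq_len(na) - 0.5) * 360 / na
  rad <- (seq_len(nr) - 0.5) * stat_extent_mm / nr
  g <- expand.grid(r = rad, a = ang)
  vals <- map_lookup(map, g$a, g$r)
  w <- if (weighted) map$disc_radius_mm + g$r else rep(1, nrow(g))
  pct_avg <- sum(vals * w) / sum(w)
  tem <- temporal_angle(map$laterality)
  in_tem <- cos((g$a - tem) * pi / 180) > 0
  tem_pct <- sum(vals[in_tem] * w[in_tem]) / sum(w[in_tem])
  sector <- vapply(EIGHT_DIRECTIONS, function(d) {
    dd <- (g$a - d + 180) %% 360 - 180
    inb <- abs(dd) < 22.5
    sum(vals[inb] * w[inb]) / sum(w[inb])
  }, numeric(1L))
  names(sector) <- paste0("deg", EIGHT_DIRECTIONS)
  structure(list(pct_avg_um = pct_avg, tem_pct_um = tem_pct,
                 sector_means_um = sector, stat_extent_mm = stat_extent_mm,
                 weighted = weighted, laterality = map$laterality),
            class = "pct_summary")
}

#' @export
print.pct_summary <- function(x, ...) {
  cat(sprintf("<pct_summary> PCT %.1f um, TemPCT %.1f um (%s, %.2f mm annulus)\n",
              x$pct_avg_um, x$tem_pct_um, x$laterality, x$stat_extent_mm))
  invisible(x)
}

#' Render a topography map to a PNG raster
#'
#' Warm colours mark thicker choroid, cool colours thinner; the disc is a
#' white hole at the center.  Rendering is deterministic for a fixed map.
#'
#' @param map A `topography_map`.
#' @param path Output PNG path.
#' @param size Image side length in pixels (default 400).
#' @param zlim Thickness range mapped to the colour scale (defaults to the
#'   map range).
#' @return Invisibly, `path`.
#' @export
render_map <- function(map, path, size = 400L, zlim = NULL) {
  stopifnot(inherits(map, "topography_map"))
  if (is.null(zlim)) zlim <- range(map$values)
  if (diff(zlim) <= 0) zlim <- zlim + c(-1, 1)
  pal <- grDevices::colorRamp(c("#313695", "#74ADD1", "#FFFFBF",
                                "#F46D43", "#A50026"))
  rmax <- map$disc_radius_mm + map$extent_mm
  px <- (seq_len(size) - (size + 1) / 2) / (size / 2) * rmax
  gx <- matrix(px, size, size, byrow = TRUE)
  gy <- matrix(rev(px), size, size)
  rr <- sqrt(gx^2 + gy^2)
  th <- (atan2(gy, gx) * 180 / pi) %% 360
  img <- array(1, dim = c(size, size, 3L))
  inside <- rr >= map$disc_radius_mm & rr <= rmax
  vals <- map_lookup(map, th[inside], rr[inside] - map$disc_radius_mm)
  z <- pmin(pmax((vals - zlim[1L]) / diff(zlim), 0), 1)
  cols <- pal(z) / 255
  for (k in 1:3) {
    plane <- img[, , k]
    plane[inside] <- cols[, k]
    img[, , k] <- plane
  }
  png::writePNG(img, path)
  invisible(path)
}
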