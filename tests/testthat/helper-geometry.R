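# Geometry fixtures built in code: annotations are constructed directly
# in physical coordinates by pairing them with a unit-scale scan
# (1 um per pixel in both axes), so pixel and um coordinates coincide.

unit_scan <- function(eye = "OD", axis = 0) {
  bscan(matrix(0.5, 8L, 8L), lateral_scale_um = 1, axial_scale_um = 1,
        scan_width_mm = 8, direction_axis_deg = axis, eye = eye)
}

poly_points <- function(x, coef) {
  y <- rep(coef[length(coef)], length(x))
  if (length(coef) > 1L) {
    for (k in (length(coef) - 1L):1L) y <- y * x + coef[k]
  }
  cbind(x, y)
}

# Flat parallel layers: inner at y_in, outer at y_in + sep, reference
# ref_off above the inner boundary.
flat_annotation <- function(x0 = 0, x1 = 3000, y_in = 1000, sep = 150,
                            ref_off = 30, step = 10) {
  xs <- seq(x0, x1, by = step)
  boundary_annotation(
    inner_boundary = cbind(xs, rep(y_in, length(xs))),
    outer_boundary = cbind(xs, rep(y_in + sep, length(xs))),
    reference_points = list(cbind(xs[xs <= x0 + 100], y_in - ref_off),
                            cbind(xs[xs >= x0 + 200], y_in - ref_off)),
    termini = rbind(c(x0 + 100, y_in - ref_off),
                    c(x0 + 200, y_in - ref_off)))
}

# Parallel layers tilted by `tilt_deg` with *vertical* separation vsep.
tilted_annotation <- function(tilt_deg, vsep = 200, x0 = 0, x1 = 3000,
                              y0 = 1000, ref_off = 30, step = 10) {
  s <- tan(tilt_deg * pi / 180)
  xs <- seq(x0, x1, by = step)
  inner <- cbind(xs, y0 + s * (xs - x0))
  boundary_annotation(
    inner_boundary = inner,
    outer_boundary = cbind(xs, inner[, 2L] + vsep),
    reference_points = list(cbind(xs[1:3], inner[1:3, 2L] - ref_off),
                            cbind(xs, inner[, 2L] - ref_off)),
    termini = rbind(cbind(xs[1L], inner[1L, 2L] - ref_off),
                    cbind(xs[3L], inner[3L, 2L] - ref_off)))
}

# Concentric circular arcs: inner on a circle of radius R, outer offset
# radially by `offset`, reference parallel to the inner (radius R - ref_off).
arc_annotation <- function(R = 6000, offset = 200, xc = 1500, x0 = 0,
                           x1 = 3000, y_apex = 1000, ref_off = 30,
                           step = 10) {
  yc <- y_apex - R                      # circle center above the layers
  arc <- function(r) {
    xs <- seq(x0, x1, by = step)
    cbind(xs, yc + sqrt(r^2 - (xs - xc)^2))
  }
  boundary_annotation(
    inner_boundary = arc(R),
    outer_boundary = arc(R + offset),
    reference_points = list(arc(R - ref_off)[1:3, ], arc(R - ref_off)),
    termini = rbind(arc(R - ref_off)[1L, ], arc(R - ref_off)[3L, ]))
}

rotate_points <- function(p, theta_deg, center = c(0, 0)) {
  th <- theta_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  sweep(sweep(p, 2L, center) %*% rot, 2L, center, `+`)
}

# Eight synthetic profiles, constant in radius with per-direction values.
constant_profiles <- function(values, extent_mm = 3.0, step_mm = 0.01) {
  stopifnot(length(values) == 8L)
  d <- seq(0, extent_mm, by = step_mm)
  lapply(1:8, function(i) {
    thickness_profile(direction = (i - 1L) * 45,
                      distance_mm = d,
                      thickness_um = rep(values[i], length(d)))
  })
}

# Analytic topography map sampled on a dense grid.
analytic_map <- function(f, extent_mm = 2.5, laterality = "OS",
                         disc_radius_mm = 0.85, da = 1, dr = 0.025) {
  angles <- seq(0, 360, by = da)
  radii <- seq(0, extent_mm, by = dr)
  vals <- outer(radii, angles, f)
  topography_map(angles, radii, vals, laterality = laterality,
                 disc_radius_mm = disc_radius_mm)
}
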