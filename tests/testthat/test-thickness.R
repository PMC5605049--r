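# Reference-curve smoothing, perpendicular sampling and thickness
# measurement against closed-form geometric oracles.

test_that("polynomial smoothing recovers exact generating polynomials", {
  # collinear points, degree 1: exact line, zero residual
  xs <- seq(0, 980, by = 20)
  cv <- smooth_reference_curve(cbind(xs, 0.5 * xs + 10), degree = 1L)
  expect_equal(cv$residual_rms_um, 0, tolerance = 1e-10)
  expect_equal(coef(cv), c(10, 0.5), tolerance = 1e-9)

  # exact quadratic data, degree 2: coefficients to 1e-9
  xs <- seq(0, 100, by = 2)
  cv2 <- smooth_reference_curve(poly_points(xs, c(5, 3, 2)), degree = 2L)
  expect_equal(coef(cv2), c(5, 3, 2), tolerance = 1e-9)
  expect_lt(cv2$residual_rms_um, 1e-9)
})

test_that("smoothing of jittered data matches lm and stays within 3 SE", {
  set.seed(421)
  truth <- c(800, -0.05, 1e-4)
  xs <- seq(0, 300, length.out = 500)
  ys <- poly_points(xs, truth)[, 2L] + rnorm(500, 0, 2)
  cv <- smooth_reference_curve(cbind(xs, ys), degree = 2L)
  ref <- lm(ys ~ xs + I(xs^2))          # independent least-squares route
  expect_equal(unname(coef(cv)), unname(coef(ref)), tolerance = 1e-6)
  se <- summary(ref)$coefficients[, 2L]
  expect_true(all(abs(coef(cv) - truth) < 3 * se))
  expect_equal(cv$residual_rms_um, 2, tolerance = 0.15)
})

test_that("smoothing rejects degenerate input", {
  expect_error(smooth_reference_curve(cbind(1:3, 1:3), degree = 4L),
               "at least")
  zig <- cbind(c(0, 10, 5, 20), c(1, 2, 3, 4))
  expect_error(smooth_reference_curve(zig, degree = 1L), "monotone")
})

test_that("perpendicular anchors are arc-length spaced and orthogonal", {
  xs <- seq(0, 100, by = 1)
  cv <- smooth_reference_curve(cbind(xs, rep(50, 101)), degree = 1L)
  per <- sample_perpendiculars(cv, interval_um = 1)
  expect_equal(nrow(per), 101L)
  expect_equal(per$nx, rep(0, 101), tolerance = 1e-12)
  expect_equal(per$ny, rep(1, 101), tolerance = 1e-12)

  # curved case: consecutive arc-length gaps within 1% of the interval,
  # checked against fine numeric quadrature of the true derivative
  coefs <- c(500, 0.2, 1e-4)
  xs <- seq(0, 2000, by = 5)
  cv <- smooth_reference_curve(poly_points(xs, coefs), degree = 2L)
  per <- sample_perpendiculars(cv, interval_um = 5)
  arc_between <- vapply(seq_len(nrow(per) - 1L), function(i) {
    xg <- seq(per$x[i], per$x[i + 1L], length.out = 200L)
    dy <- coefs[2L] + 2 * coefs[3L] * xg
    sum(sqrt(1 + ((dy[-1L] + dy[-200L]) / 2)^2) * diff(xg))
  }, numeric(1L))
  expect_true(all(abs(arc_between - 5) < 0.05))

  # normals orthogonal to tangents everywhere
  d1 <- coefs[2L] + 2 * coefs[3L] * per$x
  tang <- cbind(1, d1) / sqrt(1 + d1^2)
  expect_lt(max(abs(tang[, 1L] * per$nx + tang[, 2L] * per$ny)), 1e-9)

  expect_error(sample_perpendiculars(cv, interval_um = 1e7), "arc length")
})

test_that("thickness of flat parallel layers is the separation", {
  ann <- flat_annotation(sep = 150)
  cv <- smooth_reference_curve(ann$reference_points[[2L]], degree = 1L)
  m <- measure_thickness(cv, ann, unit_scan(), interval_um = 5)
  expect_true(all(m$valid))
  expect_lt(max(abs(m$thickness_um - 150)), 1e-6)
})

test_that("thickness between concentric arcs equals the radial offset", {
  ann <- arc_annotation(R = 6000, offset = 200)
  cv <- smooth_reference_curve(ann$reference_points[[2L]], degree = 4L)
  m <- measure_thickness(cv, ann, unit_scan(), interval_um = 5,
                         from_um = 100, to_um = 2900)
  expect_true(all(m$valid))
  expect_lt(max(abs(m$thickness_um - 200)), 0.5)
})

test_that("tilted layers give vertical separation times cos(tilt)", {
  for (tilt in c(5, 10, 20, 30)) {
    ann <- tilted_annotation(tilt, vsep = 200)
    cv <- smooth_reference_curve(ann$reference_points[[2L]], degree = 1L)
    m <- measure_thickness(cv, ann, unit_scan(), interval_um = 10,
                           from_um = 200, to_um = 2800)
    want <- 200 * cos(tilt * pi / 180)
    expect_lt(max(abs(m$thickness_um[m$valid] - want)) / want, 0.005)
  }
})

test_that("perpendiculars that miss a boundary yield invalid samples", {
  ann <- flat_annotation(x0 = 0, x1 = 3000)
  # reference wider than the boundaries: lateral overhang must flag, not
  # fabricate
  xs <- seq(-500, 3000, by = 10)
  wide <- boundary_annotation(ann$inner_boundary, ann$outer_boundary,
                              list(cbind(xs[1:3], 970),
                                   cbind(xs, 970)),
                              ann$termini)
  cv <- smooth_reference_curve(wide$reference_points[[2L]], degree = 1L)
  m <- measure_thickness(cv, wide, unit_scan(), interval_um = 10)
  expect_true(any(!m$valid))
  expect_true(all(is.na(m$thickness_um[!m$valid])))
  expect_lt(max(abs(m$thickness_um[m$valid] - 150)), 1e-6)

  # no intersection anywhere -> measurement error
  off <- boundary_annotation(ann$inner_boundary, ann$outer_boundary,
                             list(cbind(xs[1:3], 970),
                                  cbind(seq(4000, 5000, 10), 970)),
                             ann$termini)
  cvo <- smooth_reference_curve(off$reference_points[[2L]], degree = 1L)
  expect_error(measure_thickness(cvo, off, unit_scan(), interval_um = 10),
               class = "pctopo_measure_error")
})

test_that("measurement is invariant under rigid motion of the scene", {
  ann <- flat_annotation(sep = 150)
  cv <- smooth_reference_curve(ann$reference_points[[2L]], degree = 1L)
  m0 <- measure_thickness(cv, ann, unit_scan(), interval_um = 20)
  ctr <- c(1500, 1000)
  rot <- boundary_annotation(
    rotate_points(ann$inner_boundary, 10, ctr),
    rotate_points(ann$outer_boundary, 10, ctr),
    lapply(ann$reference_points, rotate_points, theta_deg = 10,
           center = ctr),
    rotate_points(ann$termini, 10, ctr))
  cvr <- smooth_reference_curve(rot$reference_points[[2L]], degree = 1L)
  mr <- measure_thickness(cvr, rot, unit_scan(), interval_um = 20,
                          from_um = cvr$domain[1L] + 100,
                          to_um = cvr$domain[2L] - 100)
  expect_lt(max(abs(mr$thickness_um[mr$valid] - 150)), 1)
  expect_lt(abs(mean(mr$thickness_um[mr$valid]) -
                  mean(m0$thickness_um[m0$valid])), 1)
})

test_that("disc center is the terminus midpoint and diameter their gap", {
  d <- locate_disc_center(c(-850, 120), c(850, 120))
  expect_equal(d$center_um, c(0, 120))
  expect_equal(d$diameter_mm, 1.70)

  d2 <- locate_disc_center(c(-900, 120), c(800, 130))
  expect_equal(d2$center_um, c(-50, 125))

  # symmetric under swapping the termini
  d3 <- locate_disc_center(c(800, 130), c(-900, 120))
  expect_equal(d3$diameter_mm, d2$diameter_mm)
  expect_error(locate_disc_center(c(1, 2), c(1, 2)), "coincide")
})

test_that("disc diameter comparison ratio and flag follow the band", {
  r <- compare_disc_diameters(1.70, 1.70)
  expect_equal(r$ratio, 1.0)
  expect_false(r$flag)
  r2 <- compare_disc_diameters(2.0, 1.6)
  expect_equal(r2$ratio, 1.25)
  expect_true(r2$flag)
  expect_equal(compare_disc_diameters(1.8, 1.5)$ratio *
                 compare_disc_diameters(1.5, 1.8)$ratio, 1)
})

test_that("direction profiles index distance from each terminus outward", {
  # flat inner boundary: arc length equals lateral span, so per-side
  # extents equal the construction parameters of the phantom
  ph <- generate_phantom_scan(phantom_spec(
    inner_coef = c(900), terminus_offset_mm = c(1.0, 0.9)))
  profs <- build_direction_profiles(ph$scan, ph$annotation, interval_um = 2)
  dirs <- vapply(profs, function(p) p$direction, numeric(1L))
  expect_setequal(dirs, c(0, 180))
  ext <- vapply(profs, function(p) p$extent_mm, numeric(1L))
  # left side (180 deg): 4 - 0.1 - 1.0 = 2.9; right: 4 - 0.1 - 0.9 = 3.0
  expect_equal(ext[dirs == 180], 2.9, tolerance = 0.003)
  expect_equal(ext[dirs == 0], 3.0, tolerance = 0.003)
  for (p in profs) {
    expect_true(all(diff(p$samples$distance_mm) > 0))
    expect_gte(p$samples$distance_mm[1L], 0)
  }

  # symmetric phantom: mirror-identical thickness sequences
  ph2 <- generate_phantom_scan(phantom_spec(
    inner_coef = c(900), terminus_offset_mm = c(0.9, 0.9)))
  pr2 <- build_direction_profiles(ph2$scan, ph2$annotation, interval_um = 2)
  ex2 <- vapply(pr2, function(p) p$extent_mm, numeric(1L))
  expect_equal(ex2[1L], ex2[2L], tolerance = 1e-6)
  n <- min(nrow(pr2[[1L]]$samples), nrow(pr2[[2L]]$samples))
  expect_equal(pr2[[1L]]$samples$thickness_um[1:n],
               pr2[[2L]]$samples$thickness_um[1:n], tolerance = 1e-3)
})
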