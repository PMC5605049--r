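# Trimming, periodic-spline interpolation across angle, and the annular
# PCT / TemPCT summaries against closed-form means.

test_that("trimming enforces a common extent and is idempotent", {
  set.seed(7)
  exts <- runif(8, 2.83, 3.18)
  profs <- lapply(1:8, function(i) {
    d <- seq(0, exts[i], by = 0.01)
    thickness_profile((i - 1L) * 45, d, rep(200, length(d)))
  })
  tr <- trim_profiles(profs, 2.80)
  expect_true(all(vapply(tr, function(p)
    abs(p$extent_mm - 2.80) < 0.01 + 1e-9, logical(1L))))
  tr2 <- trim_profiles(tr, 2.80)
  expect_identical(lapply(tr2, function(p) p$samples),
                   lapply(tr, function(p) p$samples))

  short <- profs
  short[[3L]] <- thickness_profile(90, seq(0, 2.5, 0.01),
                                   rep(200, length(seq(0, 2.5, 0.01))))
  expect_error(trim_profiles(short, 2.80), "90")
  expect_error(trim_profiles(profs[1:7]), "eight")
})

test_that("constant profiles give a constant map with PCT = TemPCT", {
  map <- interpolate_full_circle(constant_profiles(rep(200, 8)))
  expect_lt(max(abs(map$values - 200)), 1e-9)
  s <- summarize_map(map, 2.50)
  expect_equal(s$pct_avg_um, 200)
  expect_equal(s$tem_pct_um, 200)
  expect_equal(unname(s$sector_means_um), rep(200, 8))
})

test_that("a single angular harmonic is reproduced between the knots", {
  vals <- 200 + 30 * cos(seq(0, 315, by = 45) * pi / 180)
  map <- interpolate_full_circle(constant_profiles(vals),
                                 angular_resolution_deg = 0.5)
  # knot pass-through is exact
  ki <- match(seq(0, 315, by = 45), map$angles)
  for (j in seq_along(ki)) {
    expect_equal(unname(map$values[, ki[j]]),
                 rep(vals[j], length(map$radii)))
  }
  # intermediate angles within 1 um of the analytic cosine
  mid <- seq(22.5, 337.5, by = 45)
  mi <- match(mid, map$angles)
  want <- 200 + 30 * cos(mid * pi / 180)
  got <- map$values[1L, mi]
  expect_lt(max(abs(got - want)), 1)
  # no interpolation across a missing sector
  expect_error(interpolate_full_circle(constant_profiles(vals)[1:7]),
               "eight")
})

test_that("annular means match closed forms for a cosine pattern", {
  # T(theta) = 200 + 30 cos(theta), temporal meridian at 0 deg (OS):
  # whole mean 200, temporal-half mean 200 + 30 * 2/pi
  map <- analytic_map(function(r, a) 200 + 30 * cos(a * pi / 180),
                      laterality = "OS")
  s <- summarize_map(map, 2.50)
  expect_equal(s$pct_avg_um, 200, tolerance = 0.05)
  expect_equal(s$tem_pct_um, 200 + 30 * 2 / pi, tolerance = 0.1)
  expect_true(min(s$sector_means_um) <= s$pct_avg_um &
                s$pct_avg_um <= max(s$sector_means_um))
  # radial area weighting: a radius-linear pattern weights outer rings more
  mapr <- analytic_map(function(r, a) 100 + 40 * r, laterality = "OS",
                       disc_radius_mm = 0.85)
  R0 <- 0.85; E <- 2.5
  want <- 100 + 40 * (R0 * E^2 / 2 + E^3 / 3) / (R0 * E + E^2 / 2)
  expect_equal(summarize_map(mapr, E)$pct_avg_um, want, tolerance = 0.05)
  expect_equal(summarize_map(mapr, E, weighted = FALSE)$pct_avg_um,
               100 + 40 * E / 2, tolerance = 0.05)
})

test_that("laterality mirroring preserves the temporal mean", {
  f <- function(r, a) 210 + 25 * cos((a - 50) * pi / 180) + 4 * r
  od <- analytic_map(f, laterality = "OD")
  os <- analytic_map(function(r, a) f(r, (180 - a) %% 360),
                     laterality = "OS")
  expect_equal(summarize_map(os, 2.5)$tem_pct_um,
               summarize_map(od, 2.5)$tem_pct_um, tolerance = 1e-9)
})

test_that("rotating the eight directions rotates the map rigidly", {
  set.seed(11)
  vals <- runif(8, 150, 250)
  p1 <- constant_profiles(vals)
  p2 <- constant_profiles(vals[c(8, 1:7)])       # each direction + 45 deg
  m1 <- interpolate_full_circle(p1)
  m2 <- interpolate_full_circle(p2)
  shift <- match(45, m2$angles) - 1L
  idx <- seq_len(length(m1$angles) - 1L)
  expect_equal(m2$values[1L, ((idx - 1L + shift) %% (length(m1$angles) - 1L)) + 1L],
               m1$values[1L, idx], tolerance = 1e-9)
  expect_equal(summarize_map(m1, 2.5)$pct_avg_um,
               summarize_map(m2, 2.5)$pct_avg_um, tolerance = 1e-4)
  # bounded by the sample range
  s <- summarize_map(m1, 2.5)
  expect_gte(s$pct_avg_um, min(vals))
  expect_lte(s$pct_avg_um, max(vals))
})

test_that("rendering is deterministic and maps warm colours to thick", {
  map <- analytic_map(function(r, a) 200 + 30 * cos(a * pi / 180),
                      laterality = "OD")
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  render_map(map, f1, size = 120L)
  render_map(map, f2, size = 120L)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  img <- png::readPNG(f1)
  mid <- 60L
  ring <- 35L                           # pixels right/left of center
  warm <- img[mid, mid + ring, ]        # angle 0 (thick side)
  cool <- img[mid, mid - ring, ]        # angle 180 (thin side)
  expect_gt(warm[1L] - warm[3L], 0)     # red dominates blue
  expect_gt(cool[3L] - cool[1L], 0)     # blue dominates red
  unlink(c(f1, f2))
})
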