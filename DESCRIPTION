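Package: pctopo
Title: Peripapillary Choroidal Thickness Measurement and Topography from
    Radial OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automated measurement of peripapillary choroidal
    thickness (PCT) from radial optical coherence tomography (OCT)
    B-scans. A hand-drawn reference curve parallel to Bruch's membrane is
    smoothed with a polynomial fit, auxiliary lines perpendicular to the
    smoothed curve are sampled at micrometre density, and choroid
    thickness is measured as the perpendicular distance between manually
    annotated inner and outer choroid boundaries. Four cross-line scans
    through the optic disc yield eight directional thickness profiles
    that are trimmed to a common extent and joined by periodic spline
    interpolation into a full-circle thickness topography, from which
    whole-average (PCT) and temporal-half (TemPCT) summaries are
    computed. The package also implements the two-observer repeat
    measurement reconciliation protocol, lesion/fellow-eye ratio cohort
    statistics with univariate screening and multivariate ordinary
    least-squares regression, and synthetic phantom scans and cohorts
    with exact ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
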