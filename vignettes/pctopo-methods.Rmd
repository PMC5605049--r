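---
title: "Measuring peripapillary choroidal thickness: models, parameters and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring peripapillary choroidal thickness: models, parameters and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pctopo)
```

## The measurement problem

The choroid is the vascular layer between Bruch's membrane and the
sclera; its thickness is a proxy for local perfusion. Around the optic
disc (the *peripapillary* region) the retinal contour is tilted and
curved, so the naive per-A-scan (vertical) distance between the choroid
boundaries systematically overestimates thickness wherever the layers
are not horizontal. In acute optic neuritis this matters: when the disc
swells, the retinal nerve fiber layer (RNFL) around the disc thickens by
tens of percent, and the question of interest is whether the choroid
*under* the swollen region thins — a small, systematic effect that
per-eye baseline variation would otherwise swamp.

`pctopo` implements a semi-automated measurement pipeline for this
setting, together with the cohort statistics used to analyse it and
synthetic data generators that make every stage verifiable against
analytic ground truth.

## Geometry engine

The pipeline takes, per B-scan, manually annotated choroid boundaries
(inner and outer, as x-monotone polylines), a hand-drawn reference curve
parallel to Bruch's membrane on each side of the disc, and the two
Bruch's membrane termini. All geometry is performed in physical
micrometre coordinates after applying both pixel scales, so
"perpendicular" is physically perpendicular even on anisotropic pixel
grids.

1. **Smoothing.** The reference polyline is least-squares fit with a
   polynomial (`smooth_reference_curve()`). Hand tremor would otherwise
   propagate into the normal directions. The degree is configurable
   (1–8); the default is 4, which follows curvature over the ~3 mm
   per-side span without oscillating. The fit residual RMS is returned
   so callers can detect underfit. Internally the fit uses a centred and
   rescaled abscissa; raw-basis coefficients are exposed via `coef()`.
2. **Perpendicular sampling.** Anchors are spaced at a fixed
   *arc-length* interval along the smoothed curve (default 1 µm,
   `sample_perpendiculars()`). Arc length is accumulated by trapezoidal
   quadrature on a grid at a quarter of the sampling interval and
   inverted by linear interpolation; unit normals are oriented toward
   increasing depth. Sub-pixel anchors are legitimate because the
   boundaries are continuous polylines.
3. **Thickness.** For each perpendicular, `measure_thickness()`
   intersects the line with both boundary polylines (exact piecewise-
   linear intersection). Thickness is the Euclidean distance between
   the two intersections in µm. If a line crosses a boundary more than
   once, the intersection nearest the anchor is used; if it misses
   either boundary the sample is flagged invalid — values are never
   fabricated. A side is rejected when more than 20% of its samples are
   invalid, mirroring manual quality control without inventing data.
4. **Disc geometry.** The disc center is the midpoint of the two
   termini and the disc diameter their separation
   (`locate_disc_center()`). `compare_disc_diameters()` flags
   lesion/fellow diameter ratios outside 0.9–1.1 as possible margin
   mis-annotation, which is the failure mode swollen discs invite.
5. **Profiles.** Each scan contributes two directional profiles
   (`build_direction_profiles()`), indexed by distance from that side's
   terminus, i.e. from the disc margin outward. Measurable per-side
   spans land around 2.8–3.2 mm for an 8 mm scan with a ~1.7 mm disc.

### Why perpendicular measurement is the point

For parallel layers tilted by an angle $\alpha$ with vertical
separation $v$, the perpendicular thickness is $v\cos\alpha$. The test
suite checks this identity to 0.5% for tilts up to 30°, which is
exactly the error mode that per-A-scan measurement gets wrong (it
returns $v$, an overestimate of $v\cos\alpha$ by 15% at 30°).

## Topography

Eight directional profiles (four scan axes, two sides each) are trimmed
to a common radial extent (`trim_profiles()`, default 2.80 mm) and
joined across angle by a periodic cubic spline at each radius
(`interpolate_full_circle()`); radially, samples are joined linearly,
since at micrometre density there is no radial structure worth
inventing. The map reproduces its knots exactly and never extrapolates
across a missing direction.

Two reported lengths (2.80 mm and 2.50 mm, described as "diameters")
are incompatible with per-side spans of 2.83–3.18 mm if read as disc-
centred circle diameters; both are therefore interpreted as the
**radial extent of each directional profile measured outward from the
disc margin**, making the analysis domain an annulus. This is the
reading under which all the stated lengths coexist.

`summarize_map()` computes:

* **PCT** — the area-weighted mean over the annulus from the disc
  margin to the statistical extent (default 2.50 mm). The polar area
  element gives each sample weight proportional to its distance from
  the disc *center* (disc radius + radial distance). An unweighted mean
  is available (`weighted = FALSE`) for sensitivity checks; for maps
  constant in radius the two coincide.
* **TemPCT** — the same mean over the temporal 180° semicircle. Map
  angles are scan-axis angles (0° = image-right); the temporal meridian
  is resolved from laterality (OD: 180°, OS: 0°), so OD/OS pairs mirror
  correctly.
* Eight 45° sector means centred on the measured directions.

Quadrature uses midpoint cells (0.5° × extent/64 or finer) with
bilinear map lookup, so no cell center ever sits on a sector boundary
and the cosine test case integrates to its closed form
($\langle\cos\rangle_{\text{semicircle}} = 2/\pi$) to 0.1 µm.

## Observer reconciliation

Each observer measures every image three times
(`aggregate_repeats()`); the two observer means are reconciled
(`reconcile()`): disagreement is $|m_1-m_2|/\bar m$ (the symmetric
choice of denominator; the source protocol does not specify one). At or
below 10% the final value is the mean of the two; above it a third
reviewer supplies an independent mean and the final value is the mean
of the two closest of the three; a third value exactly equidistant from
both primaries averages all three (order-free and unbiased). Every
session records which rule fired, and `log_session()` appends JSON
lines for audit.

## Cohort statistics

`augment_cohort()` derives lesion/fellow (L/F) ratios — the
within-subject normalisation that removes baseline variation — plus
disc-swelling and male indicators. `classify_group()` implements the
disc-swelling rule: lesion RNFL at least 10% thicker than fellow
(ratio ≥ 1.10, inclusive; the boundary is a configurable knob because
observed group minima sit within rounding of it).

The statistical battery (`compare_groups()`, `fit_regression()`,
`screen_then_fit()`) uses pooled-variance t tests, one-way ANOVA,
Fisher's exact test for 2×2 tables and chi-square otherwise, and
ordinary least squares with listwise deletion and two-sided t tests on
coefficients. Univariate screening keeps candidates with p ≤ 0.05 and
always carries age and gender into the multivariate model (they are
controlled for regardless of univariate significance). No
multiple-testing correction is applied, matching the source analysis.
`predict_pct_ratio()` evaluates the published prediction equation for
the PCT L/F ratio with its coefficients stored as named constants:

$$\widehat{\mathrm{PCT}}_{L/F} = 1.1398 - 0.230\,\mathrm{RNFL}_{L/F}
 - 0.0674\,[\text{swelling}] - 0.017\,\mathrm{SE(D)}
 + 0.002\,\mathrm{age} + 0.001\,[\text{male}]$$

## Synthetic data

### Phantom B-scans

`generate_phantom_scan()` builds a layered grayscale image (dark
vitreous, bright retina band whose height scales with a swelling
factor, textured choroid, dim sclera, a disc gap) *and* exact
annotations: the inner boundary is a polynomial, the outer boundary its
offset along the local normal by the ground-truth thickness function
(constant, linear or single-harmonic), the reference curve the inner
boundary shifted toward the vitreous. Because offset curves share
normals, the analytic perpendicular thickness at any lateral position
is known exactly, and the phantom returns it as a callable oracle.

What the phantom does *not* emulate: speckle statistics of real OCT,
shadowing, vessel dropout, segmentation ambiguity — the boundaries are
exported exactly, noise only perturbs pixels. Passing phantom tests
therefore verifies the *measurement geometry*, not boundary drawing;
the method is semi-automated by design and boundaries are inputs.
Boundary polylines also continue smoothly under the disc gap (real
annotations would stop at the margin); this is harmless because
profiles start at the terminus and run outward. Pixels are quantized to
the 16-bit grid at generation so TIFF round-trips are bit-exact.

### Cohorts

`generate_cohort()` draws 22 optic papillitis (OP) and 20 retrobulbar
neuritis (RN) subjects by default, with per-group covariate marginals
(age, gender, laterality, refraction, IOP, visual-field defect,
autoimmune and MRI flags, fellow-eye PCT/RNFL, temporal variants) set
to the reported group means and SDs. Three generator decisions matter:

* **Observed-moment matching.** Reported moments are treated as
  *post-truncation* moments. RNFL L/F ratios are truncated at the 1.10
  swelling boundary (so generated labels always agree with
  `classify_group()`), and both the pre-truncation mean and SD are
  solved numerically so the truncated draw reproduces the reported
  mean and SD. Range-truncated covariates (age, refraction, VF,
  duration) match the mean only — an SD of 12.2 years on [20, 58] is
  unattainable by any truncated normal.
* **Equation-driven outcome.** Each subject's PCT L/F ratio is the
  published prediction equation evaluated at their covariates plus
  Gaussian residual noise; absolute lesion thickness is ratio ×
  fellow-eye draw. With the residual set to zero the generated ratios
  satisfy the equation exactly.
* **Calibrated residuals.** The source reports model R² but no residual
  variance. The shipped residual SD (0.07781 for the PCT-ratio model,
  0.52957 for the trough-BCVA model) is the value making the
  large-sample R² equal the reported one given the default covariate
  spread: $\sigma = \sqrt{\mathrm{Var}(\widehat y)(1-R^2)/R^2}$, with
  $\mathrm{Var}(\widehat y)$ estimated once from a 2×10⁶-subject
  noiseless draw (`inst/calibration/derive_sigma.R`). At the study size
  (n = 42, five predictors) the *sample* R² is expected to exceed the
  population value by roughly $p(1-R^2)/(n-1) \approx 0.04$ — the usual
  OLS optimism, visible in the replicate tests.

A `residual_rho` knob can add within-group correlation between the
residual and the RNFL ratio; its default is 0 because the equation plus
the group structure already reproduce the reported pooled correlation
(|r| ≈ 0.73), and any non-zero value would bias the recovered RNFL
coefficient away from its published value.

What the cohort generator does not emulate: treatment response over
time, repeated visits, measurement error in the covariates, or any
causal structure beyond the published regression models. Recovering the
published constants from it demonstrates that the statistical machinery
is correct and the design self-consistent — not that the clinical
findings replicate.

## Numerical choices

* Arc-length quadrature step: `interval/4`, capped at 1/64 of the
  domain; inverse interpolation is linear.
* Ray–polyline intersection is exact for piecewise-linear boundaries;
  vertical normals are special-cased.
* Periodic-spline knot values are re-imposed exactly after
  interpolation to remove spline round-off at the measured angles.
* Profile validity: invalid samples carry `NA` and a flag; radial
  interpolation uses valid samples only; >20% invalid rejects a side.
* Truncated-normal draws use inverse-CDF sampling; moment matching
  solves with `uniroot` at tolerance 1e-10.
* Degenerate inputs error early with classed conditions
  (`pctopo_schema_error`, `pctopo_measure_error`, ...), never warnings
  that fabricate values.

## Problem sizes used in verification

The shipped tests and the acceptance script use: noise-free phantoms at
2 µm sampling (the 1 µm default is supported; halving the density
changes constant-phantom results by < 10⁻⁵ µm), large-n cohorts of
20,000 subjects for coefficient recovery, and 500 replicate cohorts at
the study size (n = 42) for replicate-mean statistics. These sizes put
Monte-Carlo error well below the comparison tolerances (intercept SE at
n = 20,000 is ≈ 0.006; replicate-mean SEs are ≤ 0.002).

## Known limitations

* Automatic choroid segmentation is out of scope; boundaries are
  inputs.
* Vendor OCT container formats and DICOM are not parsed; the open
  substitute is grayscale TIFF/PNG plus a JSON sidecar.
* The topography never interpolates across a missing direction; all
  eight are required.
* The temporal-half summary assumes standard fundus orientation; scans
  acquired otherwise must say so in their metadata before the
  laterality mapping is meaningful.
* Synthetic cohorts inherit every simplification listed above; they
  are a verification instrument, not evidence about patients.
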