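# pctopo

Semi-automated measurement of **peripapillary choroidal thickness
(PCT)** from radial OCT B-scans, with full-circle thickness topography,
an inter-observer reconciliation protocol, and the lesion/fellow-eye
cohort statistics used to study choroidal thinning in acute optic
neuritis.

## Who this is for

Groups quantifying the choroid around the optic disc from cross-line
OCT scans — particularly where the disc is swollen (optic papillitis),
the retinal contour is tilted, and a naive per-A-scan (vertical)
thickness would be biased. The package also ships synthetic phantom
scans and synthetic cohorts with exact ground truth, so every stage of
the pipeline can be verified without patient data.

## The method

For each B-scan through the disc center, the choroid boundaries and a
reference curve parallel to Bruch's membrane are manual annotations
(polylines in a JSON sidecar next to a grayscale TIFF/PNG). The
pipeline then:

1. smooths the reference curve with a least-squares polynomial
   (default degree 4) to remove hand tremor;
2. drops auxiliary lines **perpendicular** to the smoothed curve at a
   fixed 1 µm arc-length interval;
3. measures thickness as the distance between each line's
   intersections with the inner and outer choroid boundaries — for
   layers tilted by α this yields the true thickness, smaller than the
   vertical distance by cos α;
4. locates the disc center as the midpoint of the two Bruch's membrane
   termini, and indexes each side's samples by distance from the disc
   margin;
5. trims the eight directional profiles (four scan axes × two sides)
   to a common 2.80 mm extent and joins them across angle with a
   periodic cubic spline into an annular topography map;
6. summarises the map over the 2.50 mm statistical annulus into PCT
   (area-weighted whole average) and TemPCT (temporal semicircle),
   resolving the temporal meridian from laterality.

Repeat measurements are reconciled with a 10% two-observer rule
(`reconcile()`), and cohort analysis recovers the published
multivariate model for the PCT lesion/fellow ratio:

```
PCT L/F = 1.1398 − 0.230·RNFL L/F − 0.0674·[disc swelling]
          − 0.017·refraction(D) + 0.002·age + 0.001·[male]
```

(`predict_pct_ratio()`, coefficients stored as named constants).

## Worked example

Measure a synthetic phantom whose choroid thickness varies as a single
harmonic (200 + 30·sin(2πx/6 mm) µm), end to end:

```r
library(pctopo)

spec <- phantom_spec(thickness = list(type = "harmonic", base_um = 200,
                                      amplitude_um = 30, period_mm = 6))
dir <- file.path(tempdir(), "scans"); dir.create(dir)
for (b in generate_phantom_set(spec)) {
  ax <- b$spec$direction_axis_deg
  write_bscan(b$scan, file.path(dir, sprintf("%d.tiff", ax)),
              file.path(dir, sprintf("%d.json", ax)),
              annotation = b$annotation)
}
res <- run_measure(dir, file.path(tempdir(), "out"),
                   run_config(interval_um = 2))
print(res$summary)
#> <pct_summary> PCT 199.5 um, TemPCT 196.3 um (OD, 2.50 mm annulus)
round(res$summary$sector_means_um, 1)
#>   deg0  deg45  deg90 deg135 deg180 deg225 deg270 deg315
#>  211.4  213.7  213.7  211.4  187.6  185.3  185.3  187.6
```

The whole average sits at the 200 µm baseline (199.5 µm after area
weighting of the asymmetric pattern), the temporal half (image-left for
this right eye) is thinner, and the sector means trace the harmonic:
thicker nasally (0°–135° sides sampled on the rising half of the sine)
and thinner temporally.

On the statistics side, a default synthetic cohort (22 papillitis / 20
retrobulbar subjects) run through the univariate screen and
multivariate fit:

```r
cohort <- generate_cohort(cohort_spec(), seed = 1)
rep <- run_cohort(cohort)
print(rep$pct_model)
#> OLS regression of pct_ratio (n = 42, R-square = 0.8129)
#>               term   estimate  p_value
#>        (Intercept)  1.1030000 1.38e-10
#>      disc_swelling -0.0561200 2.98e-01
#>  refraction_lesion -0.0227200 5.27e-03
#>         rnfl_ratio -0.2429000 2.18e-02
#>         pct_lesion  0.0005123 4.02e-02
#>                age  0.0002411 8.51e-01
#>            genderM -0.0032100 9.19e-01
```

At n = 42 the estimates scatter around the generating coefficients
(−0.230 for the RNFL ratio, intercept 1.1398); at large n they converge
to them — that convergence is what the acceptance script measures.

A thin command-line wrapper with `measure`, `cohort`,
`simulate-phantom`, `simulate-cohort` and `reconcile` subcommands is
installed at `inst/cli/pctopo.R`.

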