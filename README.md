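# pctmorph

CT morphometry of the **primary compressive trabeculae (PCT)** of the
proximal femur — the dense trabecular column running from the superior
femoral head to the medial neck cortex that remains the principal
load-bearing structure in osteoporotic hips and the preferred target for
fixation screws.

The package is aimed at musculoskeletal imaging researchers and
orthopaedic biomechanics groups. It implements, as tested reusable R
functions:

* **Anatomical landmarking** of a proximal-femur CT volume: femoral head
  sphere (center *O*, radius *R*) by robust least-squares fitting of the
  articular surface; medullary-cavity centers at the lesser trochanter's
  lower edge (*O1*) and 5 cm distal (*O3*); neck isthmus center (*O2*);
  the midcoronal plane through *O, O1, O2*; the head–neck axis (HN) via
  the *U/L/M* construction; the proximal femoral shaft axis (PFS); and
  the neck–shaft angle *NSA*.
* **Personalized threshold segmentation** at the measured mean head HU,
  **coronal sum-projection** (`Image(x,y) = Σᵢ CT(x,y,i)`), and
  binarization by per-column voxel count.
* **PCT quadrilateral extraction**: bottom boundary *AB* on the line
  tangent to the medial neck cortex and parallel to the HN-axis; top
  boundary *CD* as a chord of the head circle via tangent lines *AC*,
  *BD*; the PCT-axis through the midpoints *E*, *F*; and the scalar
  measures *α* (PCT-axis vs HN-axis), *β = 180° − NSA − α*, *δ* (signed
  offset of the PCT-axis from *O*, positive = lateral), *L-bottom*,
  *L-top*.
* **Radiograph localization**: the fitted linear models
  α = 100.51 − 0.498·NSA, δ = 13.262 − 0.101·NSA,
  L-top = −7.695 + 1.306·R, L-bottom = 0.839 + 0.799·R
  (and β = 79.49 − 0.50·NSA) evaluated on an annotated AP hip radiograph
  reconstruct the PCT quadrilateral geometrically (`localize_pct()`).
* **Synthetic data**: a voxel-level femur phantom with analytic ground
  truth (`build_phantom()`) and a parameter-level cohort simulator with
  the published distributional structure (`simulate_cohort()`).
* **Statistics layer**: normality-gated group comparison (Student's t /
  Mann-Whitney U), Pearson correlation, OLS regression, and ICC(2,1)
  reliability.

Volumes are read from NIfTI or uncompressed DICOM CT series
(`read_volume()`), in Hounsfield units, LPS world coordinates.

## Worked example

Measure a synthetic femur with known geometry, end to end:

```r
library(pctmorph)

ph  <- build_phantom(phantom_spec(spacing = 0.5), seed = 1)
rec <- measure_case(ph$volume)
rec
#> <morphometry_record> case (right)
#>   R 22.36 mm  meanHU 261.3  NSA 126.86 deg
#>   alpha 37.27  beta 15.86 deg  delta +0.21 mm  L-bottom 18.72  L-top 21.69 mm
```

The phantom was generated with R 22.25 mm, NSA 126.85°, α 37.33°,
δ 0.39 mm, L-bottom 18.62 mm, L-top 21.37 mm (the published cohort
means), so every parameter is recovered within the pipeline tolerances
(R 2 %, NSA 1°, α 2°, δ 0.5 mm, lengths 1.5 mm).

Predict and draw the PCT on a radiograph annotated with R = 26.51 mm and
NSA = 126.68°:

```r
predict_params(NSA = 126.68, R = 26.51)
#>      alpha  beta beta_identity beta_discrepancy   delta L_bottom    L_top
#> 1 37.42336 16.15      15.89664         -0.25336 0.46732 22.02049 26.92706
```

i.e. α = 37.42°, δ = 0.47 mm, L-bottom = 22.02 mm, L-top = 26.93 mm: the
axis is drawn 0.47 mm lateral to the head center at 37.42° to the
HN-axis, AB (22.02 mm) lies on the medial-cortex tangent line and CD
(26.93 mm) is the chord of the head circle bisected by the axis.

Simulate a cohort and reproduce the published correlation structure:

```r
tab <- simulate_cohort(cohort_params(n = 125), seed = 1)
cor(tab$alpha, tab$NSA)
#> [1] -0.7303729
cohort_report(tab)   # group tests, correlations, regressions, L/R ratios
```

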