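---
title: "Quantitative morphometry of the primary compressive trabeculae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative morphometry of the primary compressive trabeculae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pctmorph)
```

## The problem

The primary compressive trabeculae (PCT) form a dense column of
trabecular bone running from the superior articular surface of the
femoral head to the medial cortex of the femoral neck. In elderly,
osteoporotic femurs the PCT is the best-preserved load-bearing structure
and therefore the preferred anchoring target for fixation screws.
`pctmorph` implements a reproducible measurement chain that extracts the
PCT from a proximal-femur CT volume, reduces it to a quadrilateral on a
standardized coronal projection, and summarizes it with six scalars:

* `R` — femoral head radius (mm),
* `NSA` — neck-shaft angle (degrees),
* `alpha` — angle between the PCT-axis and the head-neck (HN) axis,
* `beta` — angle between the PCT-axis and the proximal femoral shaft
  (PFS) axis, tied to the others by the identity
  `beta = 180 - NSA - alpha`,
* `delta` — signed perpendicular distance from the head center to the
  PCT-axis (positive = axis lateral to the center),
* `L_bottom`, `L_top` — lengths of the quadrilateral's bottom and top
  boundaries.

A companion component inverts the analysis: given only the head circle
and the two axes annotated on a plain AP radiograph, fitted linear
models predict the PCT parameters and reconstruct the quadrilateral on
the radiograph (`localize_pct()`).

## The measurement chain

1. **Head sphere** (`locate_head`): outer cortical surface points near a
   seed are fitted by a least-squares sphere (algebraic fit, Gauss-Newton
   refinement, one 3-sigma rejection pass), then refined by casting ~600
   radial rays and relocating the outer cortical crossing at sub-voxel
   precision. Rays that never cross cortex (e.g. through cortical
   defects at the head-neck junction) simply drop out, which is what
   makes the estimate robust to the defect areas commonly seen there.
2. **Medullary centers** (`locate_lt_center`): axial slices perpendicular
   to a provisional shaft axis are scanned from distal to proximal; the
   lower edge of the lesser trochanter is the most distal slice whose
   medial profile bulges more than 2 mm beyond the shaft cylinder
   (a linear trend fitted to the distal reference stretch absorbs any
   residual tilt of the provisional axis). The medullary-cavity boundary
   on that slice, and on the slice 50 mm further distal, is ray-cast and
   circle-fitted, giving O1 and O3; the PFS-axis joins them.
3. **Neck isthmus** (`locate_neck_isthmus`): on the midsagittal plane of
   the neck, the position of minimum antero-posterior outer cortical
   width; O2 is the center of the inscribed circle there. A flat minimum
   is resolved at its midpoint.
4. **Midcoronal frame** (`build_frame`): the plane through O, O1, O2.
   U and L are the crossings of the head sphere with the superior and
   inferior inner neck cortex, M their midpoint, and the HN-axis the
   line M-to-O. The aux line (the PCT's bottom reference) is the line
   parallel to the HN-axis tangent to the medial neck cortex.
5. **Mean head HU** (`mean_head_hu`): mean over the disc of radius R
   perpendicular to the HN-axis through O — the personalized threshold.
6. **Segmentation, projection, binarization** (`segment`,
   `project_coronal`, `binarize`): threshold at the mean head HU, keep
   the component containing the head, resample into the midcoronal frame
   (0.5 mm), sum HU along the plane normal, and binarize by per-column
   masked-voxel count (>= 2 by default).
7. **Quadrilateral** (`bottom_boundary`, `top_boundary`, `measure_pct`):
   A and B on the aux line, C and D on the head circle via the tangent
   lines along the component's lateral and medial edges; E = mid(CD),
   F = mid(AB); the PCT-axis is EF.

### Isolating the trabecular column

A plain column-count binarization of the thresholded volume cannot
isolate the PCT: rays tangent to the head shell travel the longest
in-cortex paths, so the silhouette rim would dominate any count or sum
threshold. The package therefore peels the mask before counting: voxels
within `peel_mm` (default 3 mm) of the mask background are removed,
which dissolves thin cortical shells entirely while the slab-like PCT
interior survives. Among the resulting 2D components the one overlapping
the projected head disc the most is kept — the PCT is the most prominent
structure within the head. The peel erodes the component by a known
depth (for the L1 peel metric, `(peel_vox + 0.5) * spacing * max(|n|)`
along a face with unit normal `n`), and the measured edge lines are
shifted back outward by exactly that amount, so the reported boundary
lengths refer to the unpeeled structure.

### Finding the side edges

The quadrilateral construction needs the supporting lines of the
component's lateral and medial edges (lines AC and BD). Convex-hull
tangents turn out to be fragile here: where the thick cortical junction
between head and neck (the calcar region) survives the peel it merges
with the PCT's bottom and can protrude past the true medial edge, making
that edge concave with respect to the hull. The package instead takes,
in each 2 mm depth bin above the aux line, the extreme boundary pixel on
the requested side, runs a pairwise RANSAC over these extremes with
consensus counting, and refits the consensus set by a principal-axis
line. The junction wedge (low depth, protruding) and the rounded top
corners (high depth, receding) contaminate only the ends and are voted
out.

## The synthetic femur phantom

`build_phantom()` rasterizes an analytic right proximal femur with a
known PCT, the package's ground-truth generator:

* head: sphere of radius `R` with a cortical shell
  (`cortex_thickness`, default 2 mm), optionally with a cortical defect
  band adjacent to the head-neck junction (`defect_fraction`);
* neck: a corridor of constant in-plane half-width `0.72 R` around the
  neck axis — chosen so that the medial-cortex tangent line is exact and
  stable — whose antero-posterior half-width has a unique minimum 26 mm
  from the head center (the isthmus);
* shaft: vertical cylinder (outer radius 13.5 mm, canal radius 8 mm)
  meeting the neck axis at `NSA`, with a hemispherical lesser-trochanter
  bump (radius 9 mm) on its medial surface;
* PCT: the quadrilateral defined by (`alpha`, `delta`, `L_bottom`,
  `L_top`) extruded antero-posteriorly to 25% of the neck width on each
  side, painted at `hu_pct` wherever the voxel is cancellous;
* HU levels: cortex 800, PCT 350, cancellous 80, marrow 30, soft 0 —
  chosen so that the mean head HU falls strictly between cancellous and
  PCT levels and personalized thresholding isolates the PCT;
* Gaussian HU noise and an arbitrary rigid pose are applied last; left
  femurs are mirrored right femurs.

The defaults are the published cohort means (R 22.25 mm,
NSA 126.85°, alpha 37.33°, delta 0.39 mm, L-bottom 18.62 mm,
L-top 21.37 mm) at the scanner's 1 mm isotropic spacing. The phantom
emulates the geometry and HU contrast of a proximal femur, not real
trabecular micro-texture, tension-trabecula systems, epiphyseal scars,
beam hardening, or scanner point-spread: passing the recovery tests
shows the geometry pipeline is unbiased at realistic contrast and noise,
not that segmentation would be trivial on clinical scans.

```{r phantom, eval = FALSE}
ph <- build_phantom(phantom_spec(spacing = 0.5), seed = 1)
rec <- measure_case(ph$volume)
rec
```

Recovery is verified over the grid NSA in {115, 127, 140}, alpha in
{30, 37, 46}, delta in {-2, 0, 3} mm at 0.5 mm spacing (tolerances:
R 2%, NSA 1°, alpha 2°, delta 0.5 mm, lengths 1.5 mm; doubled under
HU noise of SD 30) — see `tests/testthat/test-acceptance.R`.

## The cohort simulator

`simulate_cohort()` generates parameter-level cohorts with the published
distributional structure: gender-specific normal head radius and mean
head HU (HU truncated to the published per-gender ranges), normal NSA,
and each response generated as its fitted-model prediction plus a
Gaussian residual whose SD comes from the variance decomposition
`sd_res^2 = sd_Y^2 - slope^2 * var_X`, so the marginal SDs equal the
published ones and the implied correlations `slope * sd_X / sd_Y`
reproduce the published r values (-0.689, -0.487, 0.623, 0.427) by
construction. `beta` is set to `180 - NSA - alpha`, which automatically
reproduces the published beta model (slope about -0.50 vs NSA) and its
correlation (about -0.69).

## Statistics layer

`compare_groups()` gates on a Lilliefors-corrected Kolmogorov-Smirnov
normality test at 0.05 per group: Student's t (pooled variance) when
both groups pass, otherwise a Mann-Whitney U test in its asymptotic
form with average ranks and no continuity correction (the convention of
the SPSS output the source analysis used; it also makes identical
samples give p = 1 exactly). `correlate()` and `fit_line()` wrap
Pearson correlation and ordinary least squares. `icc()` implements
ICC(2,1) — two-way random effects, absolute agreement, single measures —
from the ANOVA mean squares with the F-based confidence interval;
ICC(3,1) is available via `model = "ICC3"`. No multiple-testing
correction is applied, matching the source analysis.

## Numerical choices and tie-breaks

* All landmark crossings (head surface rays, U/L arcs) interpolate at
  the local half-rise level between the plateaus on either side of the
  edge, which is unbiased under interpolation blur regardless of whether
  cancellous bone or the PCT abuts the cortex.
* Cortical threshold for landmarking defaults to 300 HU; the U/L
  tracing additionally requires 55% of the local peak HU so that dense
  trabeculae are not mistaken for cortex.
* The neck isthmus position is a parabolic/midpoint refinement of the
  discrete minimum; an exactly flat width profile resolves to the
  plateau midpoint; a monotonic profile is an error.
* The mean-HU disc includes the cortical rim (full radius R), matching
  a contour drawn on the head's circular cross-section; `pct_config()`
  exposes the choice.
* `delta`'s sign is defined via the side of the HN-axis opposite the
  medial-cortex tangent line (lateral), which is well-defined on both
  CT projections and radiograph annotations.
* Side normalization: left femurs are mirrored before measurement, so
  medial/lateral and the sign of delta are defined once.
* C and D are taken on the projected head circle (the top boundary is a
  chord of the analytical circle), which makes the CT measurement and
  the radiograph localization mutually consistent.
* When the aux line is grazed rather than crossed (gap up to `gap_tol`,
  default 5.5 mm = cortex plus peel erosion), the side-edge lines are
  extrapolated onto it; a larger gap is an error that reports the gap.

## Known limitations

* The phantom's PCT has sharp boundaries and uniform HU; real PCT
  margins are gradual and the quadrilateral is an idealization.
* The DICOM reader covers uncompressed explicit-VR little-endian CT
  series only; anything else should be converted to NIfTI first.
* `locate_lt_center()` assumes the volume reaches at least 5 cm below
  the lesser trochanter; shorter volumes error out rather than
  extrapolate.
* The radiograph localization inherits the population-level regression
  scatter (residual SD about 3.1° for alpha); it predicts the expected
  PCT position, not a patient-specific measurement.
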