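---
title: "Quantifying spheroid invasion from pixels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spheroid invasion from pixels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroquant)
```

## The measurement model

`spheroquant` quantifies cell invasion from a multicellular spheroid
into a surrounding 3D matrix using two images of the same spheroid: a
nuclear-stain maximum projection at the start of culture (Day 0) and at
the end (Day 2, or any later timepoint). The analysis is deliberately
*segmentation-free*: after binarization, the foreground pixels
themselves are the unit of measurement, and no attempt is ever made to
split them into nuclei or cells. This sidesteps the well-known failure
mode of object-based pipelines on spheroids — nuclei inside the bulk
are packed too densely to segment — and makes the metrics insensitive
to cell shape changes during migration.

The procedure per spheroid:

1. **Binarize** both grayscale projections with a single global
   threshold (after contrast stretching and optional background
   subtraction).
2. **Segment the Day-0 boundary**: close small gaps, fill holes, keep
   the largest connected component, and trace its outer contour into a
   closed polygon. This polygon — unique to each spheroid — is the
   reference for every distance, which is what controls for initial
   spheroid size and shape.
3. **Align** the boundary onto the Day-2 frame by translating it so the
   Day-0 centroid coincides with the centroid of the Day-2 spheroid
   bulk. No rotation or scaling is applied.
4. **Collect outer pixels**: every Day-2 foreground pixel whose center
   lies outside the aligned polygon, with its radial distance `d` to
   the boundary (along the ray from the centroid through the pixel) and
   its polar angle about the centroid.
5. **Metrics**: area change `ΔA` (mm²), mean and maximum `d` (mm), and
   the radial area moment of inertia `I_r = Σ d² dA` (mm⁴). `I_r` is
   the second moment of the invaded area about the boundary — the same
   quantity that measures a beam's resistance to bending — and
   integrates "how much area" with "how far", weighting distant
   invasion quadratically.
6. **Directionality** (optional): PCA of the outer-pixel cloud yields
   the axes of maximum and minimum invasion; directional moments and
   mean absolute distances along those axes, and their max/min fold
   changes, quantify anisotropy (≈ 1 when invasion is radially
   uniform).

Key modelling assumptions: invasion is measured *from the boundary*,
i.e. cells are assumed to start at the spheroid edge (distances of
cells that emerged from deeper inside are underestimated); the two
images differ by a pure translation (valid when the gel does not rotate
or deform grossly between imaging sessions); and the maximum projection
adequately represents the planar distribution of nuclei.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `threshold` | 0.16 | intensity in \[0, 1\] | works well for Hoechst-stained projections; always user-adjustable since staining intensity varies by batch |
| `contrast_percentiles` | (1, 99) | percentiles | linear stretch robust to hot pixels; (0, 100) reproduces a plain min–max stretch |
| `background_sigma_px` | 0 (off) | px | Gaussian background estimate scale; enable (~20 px at 10×) when the matrix autofluoresces |
| `apply_circular_mask` | TRUE | — | crops to the inscribed circle so rectangular frames do not bias invasion towards the long axis and corners |
| `closing_radius_px` | 5 | px | bridges gaps between individual stained nuclei along the spheroid rim before contour tracing; roughly one nucleus radius at 10× |
| `pixel_size_um` | user-supplied | µm/px | taken from the run configuration, not from TIFF tags (tag dialects vary); a >1% disagreement with tags triggers a warning |
| `k` (outlier cut) | 3 | scaled MADs | conventional normal-consistent scaling (1.4826) |

Intensities are always normalized by the *dtype maximum* (255 or
65535), never per-image, so that one threshold means the same thing
across a whole batch.

## Numerical choices

- **Thresholding is strict** (`intensity > t`): a threshold of 1 yields
  an empty mask, and the set of foreground pixels is non-increasing in
  the threshold — the property behind the monotonicity tests.
- **Contour tracing at the 0.5 iso-level** (marching squares on the
  pixel-center grid, via `contourLines`). The crossing points between
  inside and outside pixel centers are essentially unbiased estimators
  of the true silhouette: on a rasterized disk of radius 50 px the mean
  vertex radius is 49.98 px and the polygon area is within 0.2% of
  `πr²`. Tracing through foreground pixel centers instead would bias
  the boundary inward by ~0.25 px and all distances outward by the same
  amount.
- **Ray rule for concave boundaries**: the ray from the centroid
  through an outer pixel can cross a non-convex polygon several times;
  the distance is measured from the *last* crossing before the pixel,
  so `d` is the penetration beyond the outermost edge the cell actually
  passed. If the intersection search fails numerically, the minimum
  distance to any edge is used and the pixel is flagged
  (`n_ray_fallback` in the metrics).
- **Points on the polygon** count as inside (even–odd rule with an
  edge tolerance of 1e-9 px), so boundary pixels are never double
  counted as invasion.
- **Alignment centroids** are mask-pixel centroids of the largest
  connected component on each day — the raw bulk, not the closed/filled
  version — so that identical masks align with exactly zero
  translation, and scattered invading nuclei cannot drag the overlap.
  The polygon's area centroid (stored separately) is the ray origin;
  for filled shapes the two differ negligibly, but both are exported
  for audit.
- **Connectivity is 8-connected** (diagonally touching foreground
  counts as one component), implemented as a union–find merge over
  EBImage's 4-connected labelling.
- **PCA degeneracies**: clouds with an eigenvalue ratio under 1.05 are
  *flagged* isotropic (the principal angle of a near-circular cloud is
  meaningless, but the fold change is still reported); exactly equal
  eigenvalues return angle 0 with the flag; a perfectly collinear cloud
  yields `I_min = 0` and an infinite fold change, flagged
  `degenerate_spread` rather than raised as an error.
- **Zero-MAD rule**: when over half the values tie at the median the
  scaled MAD is 0, and any value different from the median is flagged.
  Non-finite values (e.g. infinite fold changes) are always flagged.

## Design choices where the design was open

- **`ΔA` versus outer area.** The literal area change
  (`Area_Day2 − Area_Day0`) and the area of pixels past the boundary
  (`n_outer · dA`) coincide only when the bulk neither shrinks nor
  develops holes. Both are reported; `ΔA` may legitimately be negative
  (warned, never clamped).
- **Mean distance averages over outer pixels**, each carrying the same
  area weight `dA` — the only reading consistent with the pixel
  formalism.
- **Directional moment naming.** In the rotated frame, "invasion along
  axis u" is quantified by `Σ (coordinate-along-u)² dA`, which is the
  moment *about the perpendicular axis* (`I_y'` when u = x′). To avoid
  this classic naming trap the outputs are labelled `I_max`/`I_min` by
  meaning — spread along the maximum/minimum invasion axis — not by
  axis symbol.
- **PCA centering** uses the mean of the outer-pixel coordinates (the
  natural polar-plot center); centering on the Day-0 centroid is
  available via `center = "day0_centroid"`.
- **Directional mean distance** is the mean *absolute* transformed
  coordinate — the only sign-free choice that stays positive.
- **Outlier filtering is per metric within group**, and outliers are
  flagged, not deleted: rows stay in the consolidated table and are
  excluded only from the summary statistics, keeping the audit trail
  intact.
- **Manual artifact erasing** is replaced by an optional artifact-mask
  image (foreground = erase), discovered automatically as
  `<sampleID>_<timepoint>_artifacts.tif`; this keeps batches scriptable
  and reproducible.
- **Statistics beyond the MAD filter** (normality tests, ANOVA, post
  hoc comparisons) are intentionally left to standard tools; the
  consolidated CSV is the interface.
- The **command-line interface** is a thin `Rscript`
  (`inst/cli/spheroquant`) over `run_binarize()`, `run_quantify()`,
  `run_consolidate()` and the fixture generator; per-spheroid failures
  are logged and isolated so one bad image never aborts a batch.

## What the synthetic generator does and does not emulate

`fixture_spec()`/`generate_pair()` rasterize disk, ellipse, or polygon
spheroids and add invasion as: a uniform annulus (closed-form mean
distance and `I_r`), individually placed pixels (exact distances),
or an anisotropic Gaussian cloud (population principal angle and fold
change). `grayscale_variant()` renders flat foreground/background
intensities plus seeded Gaussian noise. Everything is deterministic
given the spec seed.

These fixtures exercise the geometry and the metric definitions
exactly, which is what the tests rely on: rasterization tolerances are
2–3% for annulus integrals (`O(perimeter/area)`), sub-degree for PCA on
dense clouds. They do **not** emulate textured nuclei, intensity decay
with gel depth, spheroid asymmetry with ragged rims, or imaging
artifacts — so passing tests validate the computations, not the
binarization threshold choice for any particular microscope or stain.
That choice remains with the user, and the threshold-monotonicity
property (lower threshold ⇒ larger area, distance and moment on the
same images) tells you which way a miscalibrated threshold biases the
results.

Problem sizes used throughout the test-suite and the acceptance script
were chosen to keep rasterization error well below the assertion
tolerances while remaining quick: 141–201 px square frames, spheroid
radii 30–50 px, annulus widths ~10–15 px, clouds of 500–2000 points,
batches of 2–5 spheroid pairs.

## Known limitations

- Distances are 2D (projected); z-resolved invasion is out of scope,
  though the machinery applies unchanged to individual z-slices.
- Invasion from cells that started deep inside the spheroid is
  attributed to the boundary, underestimating their path length.
- Pure-translation alignment cannot compensate gel rotation or
  swelling between imaging sessions.
- `ΔA` confounds migration with proliferation; the package reports the
  descriptive metrics and leaves mechanism attribution to the
  experiment design.

## A minimal end-to-end run

```{r example}
spec <- fixture_spec(image_shape = c(161, 161), pixel_size_um = 2,
                     spheroid = list(type = "disk", radius = 50),
                     invasion = list(type = "annulus", r1 = 60))
pair <- generate_pair(spec)
q <- quantify_pair(pair$day0, pair$day2)
q$metrics
q$directionality
```
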