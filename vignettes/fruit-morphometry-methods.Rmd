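---
title: "Methods: image-based fruit morphometry and mass/volume estimation"
author: "fruitmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based fruit morphometry and mass/volume estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitmorph)
```

## The problem

Grading machinery for near-ellipsoidal fruits such as *Rosa roxburghii* sorts
by mass and volume. Weighing every fruit on a balance, or measuring its
volume by water displacement, is accurate but far too slow for a line;
calipers are faster but force the operator to align the fruit's apparent
axes with the measuring direction. `fruitmorph` implements the image-based
alternative: the fruit is photographed on a contrasting backdrop, its
silhouette is extracted, calibrated dimensions and projected areas are
measured from the silhouette at *any* pose, and regression models convert
those features into mass and volume estimates.

## From photograph to silhouette

`preprocess_pipeline()` composes six stages, each exposed on its own:

1. **`adjust_color()`** — saturation gain in HSV space and an affine contrast
   stretch about the global image mean, widening the fruit/background color
   gap. Unit gains are exact no-ops.
2. **Color segmentation (optional)** — `hsv_segment()` thresholds hue and
   saturation (cast shadows are nearly gray, so a saturation floor removes
   them); `kmeans_segment()` clusters pixel colors with `stats::kmeans`,
   identifies the background as the majority cluster along the image border,
   and picks the non-background cluster whose largest connected component
   covers the image center.
3. **`gray_threshold()`** — de-shading: foreground is strictly darker (or
   brighter, a polarity flag) than a gray level. The shadow of a fruit on a
   white backdrop is an intermediate gray, so a threshold below the shadow
   luminance removes it.
4. **`median_filter()`** — a 5 × 5 sliding median (replicate border). This is
   the de-pricking step: structures at most half the window wide — the
   fruit's prickles, salt noise — vanish, while the smooth body survives.
5. **`canny_edges()`** — Sobel gradients, non-maximum suppression in the
   quantized gradient direction, hysteresis (weak edges kept only when
   8-connected to a strong edge).
6. **`trace_and_fill()`** — boundary gaps up to `gap_tolerance` px (default 5)
   are bridged by dilation, interior holes filled, the boundary position
   restored by erosion, the largest connected component kept, and thin
   protrusions removed by a morphological opening.

Two numerical choices here matter and were genuinely open:

* **Edge localization.** On a binary step the two pixels astride the step
  have tied gradient magnitudes. Suppression ties are broken toward the
  *brighter* pixel — an intensity criterion rather than a directional one, so
  the choice is invariant under image rotation and the edge stays one pixel
  thin. Even so, a Canny edge can sit on either side of a step wherever the
  tie is not exact, and filling to the edge's outer envelope would inflate
  the area by the better part of a perimeter (2–4 % for our fixture sizes).
  The pipeline therefore intersects the filled contour back with the
  de-shaded binary mask, whose step position is pixel-exact, and re-fills
  holes: the contour stage contributes component selection, gap bridging and
  de-pricking; the de-shading stage owns the boundary.
* **Stage order.** Whether de-shading precedes de-pricking cannot be settled
  from the method narrative alone; the pipeline thresholds first and medians
  the resulting 0/255 image, which lets one median pass remove prickles and
  salt noise together. The segmentation method (`"gray"`, `"hsv"`,
  `"kmeans"`) and every threshold are configuration, not constants.

The pipeline is exactly equivariant under 90° image rotation (a tested
property), and K-means segmentation is made deterministic and
rotation-equivariant by presenting pixels to the clusterer in canonical
(lexicographic RGB) order under a fixed seed.

## Calibrated measurement

A `camera_calibration(mm_per_px, mm2_per_px)` carries the bench's length and
area ratios; the two must agree within 5 % (`mm2_per_px ≈ mm_per_px²`). The
bundled `reference_calibration()` — 0.126 mm/px and 0.016 mm²/px — satisfies
this (0.126² = 0.0159).

**Projected areas** are foreground pixel counts times `mm2_per_px`, reported
in cm². Across the three orthogonal views (X-side, Y-side, Z-top) the
criterion projected area is the plain mean, `CPA = (PA1 + PA2 + PA3)/3`.

**Axes by rotation scan.** `measure_axes()` rotates the silhouette over
[0°, 180°) in `step_deg` steps (default 1°; the step must divide 180) and
measures, at each pose, the longest contiguous horizontal run of foreground
pixels. The maximum over poses is the long-axis chord `L1`; the minimum is
the short-axis chord `L3`; half axes are `a = L1·mm_per_px/2`,
`b = L3·mm_per_px/2`. For an ellipse with semi-axes (a, b) whose major axis
makes angle ψ with the horizontal, the longest horizontal chord is
`2ab/√(a² sin²ψ + b² cos²ψ)`, which is maximized (2a) and minimized (2b)
over ψ — the scan finds both regardless of how the fruit lay under the
camera. Ties in the maximizing angle go to the first attaining angle
(this affects only the reported angle, never the lengths). Rotation is
nearest-neighbor resampling about the foreground centroid with the canvas
expanded so nothing is clipped; on fixtures with semi-axes ≥ 30 px it
changes the pixel count by under 1 %.

`measure_fruit()` measures all three views jointly: `L1` is the global
maximum chord and `L3` the global minimum across views — the most
significant half-long and half-short axes of the three view ellipses.
Per-view measurements are attached for users who want them. Geometric
volumes use the axes in cm so they land in ml:

$$V_\mathrm{ellip} = \tfrac{4}{3}\pi a^2 b, \qquad
  V_\mathrm{parab} = \tfrac{4}{3}\pi a b^2, \qquad
  V_\mathrm{parab}/V_\mathrm{ellip} = b/a .$$

`slice_integrate_area()` implements the bench reference measurement (sum of
circular sectors `Δθ·πr²/360` around a closed profile; the step angles must
sum to 360°) and `mean_relative_error()` the percent MRE used to compare
image areas against it.

## Estimation models and metrics

`fit_model()` fits `linear`, `quadratic`, `exponential` (`k1·e^{k2 x}`),
`power` (`k1·x^{k2}`), and the two multivariate forms (`M or V ~ a, b` and
`~ PA1, PA2, PA3`). Linear-in-parameters forms use ordinary least squares;
exponential and power forms are true nonlinear least squares on the original
response scale (`minpack.lm::nlsLM`), initialized from the log-linearized
OLS fit — the selection criteria are residuals in grams/ml, not log units,
so the log fit alone would optimize the wrong objective.

`fit_metrics()` implements the four selection metrics:

* `R² = 1 − SSE/SST`;
* `RMSE = √(SSE/n)` — denominator `n`, not `n − p`; this is the convention
  the bundled reference metrics are consistent with;
* `χ² = Σ (yᵢ − ŷᵢ)²/ŷᵢ` — a Pearson-style statistic. The ratio χ²/SSE in
  the reference tables is approximately 1/mean(response) across models,
  which identifies this form; it is documented as a convention and never
  used as a cross-check target;
* accuracy `φ = (100 − RMSE)/100 × 100 %` — taken literally from its
  definition even though it mixes units (an RMSE in grams subtracted from a
  pure number); it is a reporting convention, monotone in RMSE.

`rank_models()` orders by R² descending with χ² then RMSE as ascending
tie-breaks, stably. `reference_models()` holds all 65 published models
(coefficients and printed metrics) keyed by response, form and predictors;
the published tables list one dimension-based mass model twice and omit the
exponential-in-`a` mass row, so that slot genuinely does not exist, and the
two geometric-volume rows (V estimated directly by `Vellip`/`Vparab`) are
stored as identity models without fitted constants. `grade_fruit()` assigns
Small/Medium/Large by mass, with default class boundaries at the midpoints
between the published per-category extremes (14.62 g and 19.465 g) and outer
bounds at the published minimum and maximum (10.73, 29.76 g) — midpoints
because the categories' printed ranges do not touch, and a boundary centered
in the unobserved gap treats both neighbors symmetrically.

## The synthetic-fruit generator

No per-fruit raw data are distributed with the reference study, so the
package carries a generator with two layers.

**Rendered images** (`render_fruit_photo()`): an ellipse of known semi-axes
at arbitrary pose, plus the three nuisances the pipeline must remove —
radial triangular prickles (28 by default, ≤ 10 px long, ≤ 2 px wide, evenly
spaced base angles with jitter so neighboring spikes never merge into
structures a 5 × 5 median cannot remove), an offset desaturated shadow at
80 % background brightness, and salt/pepper noise. The ground-truth mask is
the bare ellipse; every render carries its analytic truth (axes, pose,
πab). Under these conditions the raw thresholded mask differs from truth by
more than 2 % (the prickles are really there) while the pipeline mask
differs by less than 2 % and the recovered axes by less than 3 % — the
de-pricking demonstrably works.

**Population tables** (`generate_population()`): the fruit body is an oblate
spheroid — equatorial half axis `a ~ N(19.72, 2.24²)` mm, polar half axis
`b ~ N(14.76, 1.38²)` mm (draws rejected until `0 < b < a`). Projections
follow: top view `PA3 = πa²(1+ε_top)`, side views
`PA1 = PA2 = πab(1+ε_side)` with independent noise per view. Measured
volume is `V_parab(1+ε_V)` and mass is `ρ·V_ellip(1+ε_M)`, with the density
ρ solved from moment matching — `E[M] = ρ·(4π/3)·(μ_a²+σ_a²)·μ_b` — so the
expected mass equals the configured 18.01 g exactly (ρ ≈ 0.74 g/ml). This
geometry reproduces the reference population's summary statistics (top area
π·1.972² ≈ 12.2 cm², side areas ≈ 9.1 cm², mean volume ≈ 18 ml) and the
qualitative finding that the ellipsoid volume tracks mass while the
paraboloid volume tracks measured volume.

Noise scales were fixed once from the reference coefficients of variation:
mass CV ≈ 30 % and volume CV ≈ 31 % exceed what axis variation alone
produces (≈ 25 % and 22 %), so `noise_mass = 0.17` and `noise_volume = 0.22`
model genuine density and measurement scatter. Area noise is asymmetric —
2 % on the smooth side profiles, 6 % on the top view, where the fruit's
irregular sepal crown departs most from the ellipse idealization. The
asymmetry also carries a correlation consequence: the side views share both
axes, so corr(PA1, PA2) ≈ cv²_shared/(cv²_shared + cv²_noise) ≈ 0.98 is the
largest off-diagonal correlation, as observed on real fruits, whereas with
equal small noise everywhere the nearly deterministic a → PA3 link would
dominate. With all noise scales zero the defining identities hold exactly
(`CPA` is the exact mean, `V_parab/V_ellip = b/a` row-wise, `M = ρ·V_ellip`),
which is what makes the end-to-end regression-closure tests exact.

All randomness flows from one explicit seed through a local RNG scope, so
generation never perturbs the caller's RNG state and repeat runs are
bit-identical.

**What the generator does not emulate:** real fruits are not true spheroids
(lobes, asymmetry), illumination is not uniform, shadows are soft-edged,
prickles vary in thickness, and backgrounds are textured. Passing tests
therefore demonstrate that the algorithms are implemented correctly and are
robust to the modeled nuisances — not that segmentation thresholds
transfer to any particular camera or lighting; those are configuration to be
tuned per bench.

## Problem sizes and numerical conventions

The test-suite and acceptance fixtures use ellipse semi-axes of 30–90 px on
canvases around 150–260 px, rotation scans at 1–2° steps, populations of
25–500 fruits, and one 10⁴-point fit for the RMSE-consistency property —
sizes at which every geometric quantity is still resolved to well under the
tested tolerances while the whole suite runs in about a minute on one CPU.
Other conventions: masks are strict 0/1 integer matrices, row-major with
origin at the top-left pixel and angles counter-clockwise; image filters use
replicate borders; chords are longest contiguous runs (robust to stray
holes); all model JSON is written at 17 significant digits so round trips
are bit-exact.

## Known limitations

* Single fruit per image; overlapping or touching fruits are out of scope
  (the largest-component rule silently keeps the biggest blob).
* The reference regression metrics cannot be recomputed here — the 60 real
  fruits' raw data were never deposited — so the registry stores printed
  values, and the acceptance checks recompute only the closed-form
  identities among them plus synthetic-fixture properties.
* `φ = 100 − RMSE` is dimensionally awkward by construction; compare models
  fitted to the same response only.
* Nearest-neighbor rotation quantizes chord lengths to whole pixels; at the
  default 1° step the induced axis error is ≤ 2 px on ≥ 60 px axes, which is
  the accuracy floor of the method as implemented.
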