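---
title: "AVLR morphometry: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AVLR morphometry: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avlr)
```

## The quantity being measured

The arteriovenous length ratio (AVLR) compares the length and tortuosity
of retinal arteries against veins within an annular region around the
optic disc. For a length/tortuosity metric $m$ computed per vessel
segment, the image-level feature is

$$\mathrm{AVLR}_m \;=\;
\frac{\overline{m}_{\text{artery}}}{\overline{m}_{\text{vein}}},$$

an *unweighted* arithmetic mean over segments in each class. Nine metrics
are used: chord length, arc length, distance metric (DM), two inflection
count metrics (ICM, ICMb), sum of angles metric (SOAM), normalized total
curvature (NC), standard deviation of absolute curvature (SDAC), and the
smoothed centerline length (CL). In balanced, healthy vasculature the
ratios cluster near 1; one-sided elongation or tortuosity moves them away
from 1 with a sign that identifies which class changed. Segment-wise
ratios (each segment's metric divided by the opposite-class image mean)
provide the per-segment counterpart; by construction the mean of the
artery segment-wise ratios equals the image-level ratio.

Unweighted means are used because the image-level features are defined as
plain averages over segments; a length-weighted variant would conflate
the length metrics with the weighting. Segments classed `unknown`
(typically artery/vein crossings) and segments shorter than 5 pixels are
excluded from both class means so crossings cannot bias either class.
When a ring contains no usable segment of one class, the ratios are
flagged missing rather than propagating division errors — small 2–3 ROD
rings can genuinely lack one class.

## Pipeline stages and their parameters

### Optic disc

The disc is the brightest large structure in a fundus image. The detector
converts RGB to grayscale (luminance weights 0.299/0.587/0.114),
thresholds at an intensity quantile (`brightness_quantile`, default
0.995), opens with a disc-shaped structuring element
(`od_opening_radius`, default 5 px) to remove speckle, and takes the
centroid and equivalent radius $\sqrt{A/\pi}$ of the largest component at
least `min_area` (default 100 px) in size. A quantile rather than a fixed
threshold adapts to exposure; the equivalent radius is robust to ragged
component edges. The disc radius defines the ROD unit; everything
downstream is scale-free in ROD. A manual override (`manual_od()`,
`od_manual` in the config) covers pathology that obscures the disc.

### Ring ROIs

Rings are half-open Euclidean annuli $[a R, b R)$ on pixel centers, with
the standard factor pairs (2, 3) and (2, 5). Half-open intervals make
adjacent rings sharing a radius partition exactly. Vessels crossing the
ring boundary are truncated at the last inside pixel — the simplest
reading of a "ring cut"; keeping whole intersecting segments would blur
the ROI definition and is intentionally not the default.

### Skeletonization

The union of all non-background label pixels (arteries, veins, and
`unknown` crossings, so crossings do not sever connectivity) is thinned
with Zhang–Suen parallel thinning. Zhang–Suen alone leaves staircase
pixels with 3–4 neighbors on diagonal runs, which inflates chain-code
lengths by over 10% and corrupts turning angles, so a sequential cleanup
pass follows: any pixel with at least two neighbors whose foreground ring
neighborhood forms a single 8-connected component (an *8-simple* pixel)
is deleted, in raster order, until a fixpoint. Interior path pixels are
not 8-simple and endpoints are protected, so exactly the redundant
staircase/corner pixels disappear and the skeleton is strictly unit
width; connectivity is preserved by the definition of a simple point.

Spur removal (`min_spur`, default 10 px) deletes endpoint-terminated
twigs shorter than the threshold that attach to a branch point. Each
round collects every qualifying twig against the current skeleton and
deletes them together; rounds repeat to a fixpoint. The parallel-per-round
rule is stated explicitly because sequential one-at-a-time deletion is
order-dependent (removing one twig can change whether a neighboring twig
still terminates at a branch point). Free endpoint-to-endpoint segments
are never deleted, whatever their length.

Branch points are skeleton pixels with ≥ 3 skeleton neighbors. Thinning
produces small clusters of such pixels at crossings; clusters are
collapsed to a single representative so one crossing counts as one
junction. Removing *all* branch-cluster pixels decomposes the remainder
into simple paths (a pixel that still had 3 neighbors afterwards would
itself have been a branch pixel), each ordered end-to-end. A segment's
class is the pixel-majority class with ties resolving to `unknown`.
Finally, segments whose both ends touch branch clusters and whose arc
length is at most `max_junction_len` (default 5 px) are discarded: these
are the short "L"-shaped connectors thinning fabricates where vessels
cross, not anatomy. Pixel accounting (skeleton = segments + branch
clusters + dropped) is maintained and asserted in the tests.

Defaults (`min_spur` 10 px, `max_junction_len` 5 px) are set at the scale
of ~2000-pixel fundus rasters and are ordinary config keys.

### Discrete curve metrics

All metrics operate on the ordered pixel path of one segment.

* **chord** — Euclidean distance between the path ends. A degenerate
  closed path would make ratios divide by zero, so the chord is clamped
  to $10^{-6}$ px and the segment flagged.
* **arc** — the chain-code sum (1 per orthogonal, $\sqrt2$ per diagonal
  step). Chain-code length systematically overestimates the true curve
  length: the bias is zero for axis-aligned and 45° digital lines, peaks
  at 8.2% near 22.5°, and averages about 3% over orientations of a
  smooth curve. This bias is inherent to the estimator, not noise, and
  is quoted wherever arc-based quantities are validated.
* **smoothing** — path coordinates are smoothed by a symmetric moving
  average of width `smooth_window` (default 5, endpoints retained by
  shrinking the window symmetrically). Tangents are per-interval unit
  differences. The signed curvature at an interior point is the turning
  angle between consecutive tangents divided by the mean local step —
  with the turning computed from the *unwrapped tangent-angle series
  smoothed by a moving average of width `2·window − 1`*. The second
  (angle-domain) smoothing is what makes turning sums usable on rasters:
  on digitized semicircles of radius 30–100 the raw consecutive-tangent
  turning overestimates the total turning 1.5–3×, while the angle-
  smoothed estimator is within 4% of the analytic $\pi$, and it leaves
  genuinely straight paths with exactly zero curvature (a moving average
  of a constant angle is constant).
* **DM** = arc / chord (≥ 1, equality iff collinear).
* **inflections** — sign changes of the smoothed signed curvature, where
  |curvature| below `curvature_zero_tol` (default $5\times10^{-3}$
  px$^{-1}$, i.e. a radius of curvature beyond 200 px counts as
  straight) is treated as zero and sign runs shorter than
  `inflection_min_run` (default 5 samples) are discarded. The run filter
  is a debounce: near an inflection the curvature crosses zero slowly
  and rasterization chatter would otherwise produce spurious extra
  crossings. These two defaults were fixed by examining rasterized
  k-period sines at several orientations; across a tolerance decade
  ($10^{-3}$ to $2\times10^{-2}$) the counts are stable at the analytic
  $2k-1$.
* **ICM** = (inflections + 1) · DM, so a zero-inflection curve reduces
  to DM rather than annihilating it; **ICMb** uses the classical
  large-flip criterion instead (squared difference of consecutive unit
  normals > 1, normals evaluated only on the debounced curvature sign
  runs where they are well defined).
* **SOAM** = Σ|turning| / arc; **NC** = Σ|curvature|·(local step) / arc.
  Because the discrete curvature *is* the turning divided by the local
  step, NC coincides with SOAM under this discretization; both are
  reported because they are defined and named independently, and the
  equality is a property of this estimator, not an identity of the
  underlying continuous quantities.
* **SDAC** — standard deviation of pointwise |curvature|.
* **CL** — the polyline length of the smoothed subpixel path. Arc and CL
  are deliberately distinct estimators of segment length: arc is the
  raw chain-code sum (positively biased), CL the smoothed length (small
  negative bias from corner-cutting); on phantoms CL is within 5% of the
  true length including the worst orientations, typically within 2%.

Angles are radians internally; SOAM per pixel of arc. Paths shorter than
5 pixels cannot support the curvature stencil and are flagged
`too_short`, keeping chord/arc/DM but reporting curvature metrics as
missing.

## The eye comparison

Left/right reports carry, per metric: the difference (right − left), the
log-ratio, and the asymmetry index $|r-l| / \frac{r+l}{2}$, which is
bounded in [0, 2] and symmetric in the sides; an index near 2 means one
side's ratio dwarfs the other's. The cohort test is a paired Wilcoxon
signed-rank test with zero differences dropped; it is nonparametric
because the empirical AVLR distributions are right-skewed. All-tied
cohorts report p = 1 with a `degenerate` flag rather than an error. No
multiple-testing correction is applied across the nine metrics; raw
p-values are reported per metric.

## The phantom generator

`render_phantom()` rasterizes a bright uniform disc on a dark background
plus parametric curves (line, circular arc, sine, cubic Bézier) at a
given stroke width in their class colors, without anti-aliasing or
jitter, so rendering is bit-deterministic. Ground truth (chord; arc by
dense 10⁴-sample polyline integration; inflection count analytic for
lines/arcs/sines and numeric for Béziers; total turning; mean
|curvature|) is computed purely from the parametric form and never
touches the raster or any pipeline code — it is an independent oracle.

`sample_population()` emulates a screening cohort: per image, 5–15
arteries and 5–15 veins as horizontal sine strokes in disjoint bands
(no crossings, so per-stage behavior stays isolated; crossings are
exercised separately), lengths LogNormal(log 120, 0.3) pixels, artery
lengths times `artery_scale`, amplitudes 3.3–8.3% of curve length times
`tortuosity_level`, 1–2 periods, width 3 px, disc radius 38 px in a
reserved band. Amplitude is proportional to length so that scaling a
class's lengths by $k$ scales its *arc* lengths by exactly $k$ —
otherwise shorter curves would be relatively more tortuous and the
imposed length ratio would not be the recovered quantity. At
`artery_scale = 1` this reproduces the balanced-vasculature regime in
which the ratio distribution centers on 1.

What the phantoms do **not** emulate: vessel width variation and taper,
branching trees (curves are unbranched except in dedicated junction
tests), intensity texture, label noise at vessel borders, pathology, and
anti-aliased labels (a separate palette-tolerance mode covers that).
Passing phantom tests therefore certifies the geometry pipeline —
skeleton, segmentation into fragments, metric estimators, aggregation
arithmetic — not robustness to imperfect upstream segmentation.

## Numerical choices and degenerate inputs

* Coordinates are 1-based `(row, col)`, row increasing downward.
* Empty label maps yield empty skeletons and `incomplete` records, never
  errors; batch runs isolate per-image failures and always write partial
  results, signalling partial failure in the exit status.
* Single-pixel fragments between adjacent junctions cannot form a valid
  path (length ≥ 2) and are dropped into the accounting's `n_dropped`.
* Palette matching is nearest-color within a per-channel tolerance
  (default 30), fallback class `unknown`; label colors are configuration
  because labeling conventions vary by dataset.
* CSVs serialize doubles at full precision (15 significant digits);
  reruns on identical inputs are byte-identical.

## Validation tolerances and known limitations

The test suite validates against analytic truth at tolerances that match
the estimators' documented biases: semicircle DM within 6% and SOAM
within 10% of $1/r$ (orientation-averaged chain-code bias plus residual
turning noise); arc within 9% and CL within 5% of dense-quadrature truth
(covering the 8.2% worst-case chain-code orientation and ~1.5 px of cap
erosion per stroke end from thinning); cohort medians of
`avlr_arc`/`avlr_cl` within 10% of the imposed scale; rotation stability
at 5% for the geometry-dominated metrics (chord, DM, ICM, ICMb, CL) and
8% for the chain-code/angle metrics (arc, SOAM, NC). SDAC — a second
moment of pointwise curvature — is dominated by rasterization noise for
gently curved vessels and is only checked to order of magnitude; its
*ratios* remain informative because both classes share the same noise
floor, but absolute SDAC values should not be compared across imaging
resolutions.

Further limitations: the OD detector assumes the disc is the largest
bright component (pathologies like severe exudates can defeat it — use
the manual override); segment class is pixel-majority, so a mislabeled
crossing region can flip short segments to `unknown`; and no vessel
width/caliber is measured — the classical AVR is a different, caliber-
based biomarker outside this package's scope, as are disease grading and
any learning on the feature set.
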