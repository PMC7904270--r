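---
title: "Methods: snakuscule iris localization and head-pose-augmented gaze mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snakuscule iris localization and head-pose-augmented gaze mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazetrackr)
```

# The problem

A single webcam under natural light sees a face at low resolution: an iris
spans a handful of pixels, there is no infrared glint to anchor on, and
the head moves freely. Feature-based gaze tracking in this regime works
from three measurements per video frame — the iris centers, a stable
facial reference point, and the head pose — and regresses the on-screen
point of regard (POR) from them after a short calibration phase. This
vignette documents the models, parameters and numerical conventions this
package fixes, and what its synthetic benchmarks do and do not establish.

# Iris-center localization

## The snakuscule energy

The probe is a circle pair centered at `p`: an inner disk of radius `r`
and an outer annulus out to `βr`. Its score is the gray contrast

    G(p) = mean{ f(q) : r < |q − p| ≤ βr } − mean{ f(q) : |q − p| ≤ r },

with `f` the gray value and membership decided by the Euclidean distance
of each pixel center — no fractional border weighting. Means (not sums)
make `G` independent of the annulus/disk area ratio and hence of β's
area effect; `G` is invariant under adding a constant to the image and
scales linearly with contrast. A dark iris on a lighter sclera maximizes
`G` when the disk coincides with the iris.

Eye ROIs are much wider than tall, so the annulus generally pokes past
the top and bottom ROI rows even at the optimum. The probe is therefore
required to fit inside the ROI *laterally* only (that is what the scan
range enforces); vertically the regions are truncated at the image rows,
exactly as a circular probe behaves inside a tight eye crop. The
brute-force oracle used throughout the test-suite — region membership
recomputed per candidate from a full-image distance matrix — has this
behavior by construction, which is one reason truncation is the right
convention: the fast path and an independent exhaustive search must agree
exactly, with no boundary special-casing.

## Anatomical initialization instead of snake evolution

Classic snakuscules grow or shrink iteratively. Here the inner radius is
fixed per ROI: adult iris radius is ~7 mm, the eyeball diameter 24–26 mm,
and a landmark-tight eye ROI is about an eyeball wide, so

    r = round(α N),   α = 0.25 by default,

with `N` the ROI width after ×2 magnification. Rounding is half-up
(`floor(x + 0.5)`): base R's round-half-even would make `r` depend on the
parity of `N`, an avoidable discontinuity. A 1-D integer scan along the
horizontal centerline `y = ⌊M/2⌋`, `x ∈ [⌊βr⌋+1, N − ⌊βr⌋]`, finds the
rough center (the iris straddles the centerline in any tight eye crop);
an exhaustive `(2δ+1)×(2δ+1)` integer grid around it yields the final
center. Sub-pixel refinement is deliberately excluded: the scan is
integer-grid, which keeps the exhaustive oracle exact.

Tie-breaks are fixed so results are deterministic: the scan keeps the
smallest x; refinement keeps the candidate nearest the rough center, then
the first in row-major order. Ties occur with zero-noise synthetic images
(and, notably, whenever the initialized radius falls below the true iris
radius, which creates an energy plateau — see *Limitations*).

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| α | iris radius / ROI width | 0.25 | anatomy; also the benchmark-sweep optimum |
| β | outer/inner radius ratio | 1.4 | sweep optimum on the localization benchmark |
| δ | refinement half-width (px) | 2 | 2 outperforms 1 on gaze error downstream |
| scale | ROI magnification | 2 | bilinear; nearest available for exactness tests |

The sweep grids mirror the benchmark protocol: α 0.21–0.25 (step 0.01 —
the protocol's stated step of 0.05 cannot produce a grid on that
interval, so the finer step is the package default and configurable),
β ∈ {1.32, …, 1.52} step 0.04, δ ∈ {1, 2, 3, 4}.

# Eye ROI and anchor point

ROI rectangles come straight from the landmark scheme: left eye
`x ∈ [P43x, P46x]`, `y ∈ [min(P44y, P45y) − 3, max(P47y, P48y) + 3]`,
right eye analogously from points 37/40 and 38, 39/41, 42. The ±3 px
margins are applied in original-image pixels, before magnification, and
are kept fixed regardless of resolution (the protocol states them as
absolute pixels). Grayscale erosion uses the radius-1 Euclidean disk,
i.e. the 3×3 cross — the smallest disk, and the common morphology
default. Color conversion uses ITU-R BT.601 luma weights. ROI
coordinates map back to the full image by `p_image = origin + p_roi / scale`.

The anchor point is the arithmetic mean of the 36 stable landmarks —
all 68 minus the 12 eye and 20 mouth points, which move with gaze and
speech. Averaging 36 points suppresses per-landmark jitter by roughly
√36 = 6 relative to a single eye-corner anchor, and the mean stays
defined under partial occlusion. The subset is configurable; 1–36 is the
default because jaw + brows + nose are exactly the non-eye, non-mouth
indices. Eye vectors are raw pixel differences `p_iris − p_anchor`;
inter-ocular normalization is available behind a flag but off by default
(the calibration regression absorbs scale for a fixed head distance).

# Head pose

Pose is solved from six rigid landmarks (chin 9, nose tip 31, outer eye
corners 37/46, mouth corners 49/55) against a documented constant 3D
model: nose tip at the origin, bilaterally symmetric, rounded adult
anthropometry (e.g. outer eye corners at (±45, −34.5, 27.5) mm). The
solver is Levenberg–Marquardt on the reprojection residuals over
(pitch, yaw, roll, t), initialized from a weak-perspective guess (depth
from the inter-ocular distance ratio). The contract is the reprojection
minimum, not the solver identity; any minimizer reaching it is
equivalent.

Conventions, fixed because the mapping consumes raw angles: camera frame
x right, y down, z forward; intrinsic rotations pitch(x)→yaw(y)→roll(z);
angles in degrees, normalized to (−180, 180]. Uncalibrated cameras use
f = image width, principal point = image center. The true 3D head model
of any given person is unknown and unknowable here, so all pose accuracy
claims are synthetic round trips (project the model at a known pose,
re-estimate): they verify the solver and conventions, not anthropometry.

# Gaze mapping, fusion, and metrics

Each screen axis gets its own polynomial in
`(e_h, e_v, h_p, h_y, h_r)`. The six presets are nested term lists:

* No.1 `{1, e_h, e_v}`; No.2 adds `e_h·e_v, e_h², e_v²`
* No.3/No.4 = No.1/No.2 + `{h_p, h_y, h_r}`
* No.5/No.6 = No.3/No.4 + `{h_p², h_y², h_r²}`

Defaults: preset 4 horizontally, preset 2 vertically (the combination
that minimizes benchmark gaze error; adding pose helps the horizontal
axis, where yaw dominates, and not the vertical, where the eye vector
already carries the pitch information). Fits are ordinary least squares
via QR, with the residual RMS and design condition number kept as
diagnostics; rank deficiency reports the collinear terms by name.

Binocular fusion is the convex combination `g_f = w·g_L + (1−w)·g_R`,
default w = 0.5 on both axes (per-axis weights are accepted, since the
benchmark optimum differs slightly by axis — 0.5 horizontal, 0.6
vertical — but a single 0.5 is the protocol default). An occluded eye
collapses w onto the other eye.

Angular errors are measured from the 3D eyeball center: with unit gaze
vectors toward the true target and the estimated screen point,
H is the unsigned angle between their x–z projections (an azimuth
difference computed wrap-free from atan2 of cross and dot, immune to the
±180° seam of rays pointing back from the eyes toward the screen plane),
V the unsigned elevation (asin v_y) difference, and C = √(H² + V²).
The root-sum-square form is deliberate: the published per-preset table
prints H = 5.7, V = 4.0 combining to C = 7.0, which only the
root-sum-square satisfies, although its caption calls C a "sum of
squares". For the fused estimate the reference point is the w-weighted
combination of the two eyeball centers — so w = 1 and w = 0 reproduce
the single-eye pipelines bit for bit, and w = 0.5 measures from the
cyclopean midpoint.

The evaluation protocol splits each session at the first `n_calib`
*detected* frames (default 1000); undetected frames count only toward
the total TF, and the detection rate DF/TF is recomputable from the
frame table. Reports round to one decimal degree; CSV outputs keep full
precision.

# The synthetic data, and what it shows

`render_eye_roi()` draws a hard-edged dark disk (iris, default gray 60)
on a lighter field (sclera/skin, 200), with optional top eyelid band,
Gaussian pixel noise, specular highlight, and a 1-px anti-aliased rim
behind a flag (hard edge is the default so region means are analytically
checkable). Default radius is 0.25 of the ROI width — the anatomical
ratio the initialization assumes. Benchmarks draw ROI sizes of 52–68 ×
32–42 px, centers in the middle of the ROI and within 2 px of the
vertical centerline, as in real landmark-tight crops.

`simulate_session()` works in mapping space: targets are drawn uniformly
on a 520 × 320 mm screen lying in the camera's z = 0 plane, eyeballs sit
at (±32, −30, 600) mm (a desk-distance viewer), head pose follows smooth
sinusoids of amplitude (10, 15, 6)° with incommensurate periods (97,
131, 73 frames) so the pose terms are never collinear, and per-eye eye
vectors are obtained by Newton-inverting the ground-truth polynomial
(residual < 1e−12, from the linear-terms inverse as a start). The
ground-truth coefficients put dominant linear gains of 8–9 mm/px on the
matching axis, small curvature and interaction terms, moderate pose
gains, and slightly different gains per eye. Generating in mapping space
makes coefficient recovery an exact end-to-end check: a zero-noise
session must evaluate to numerically zero gaze error, and it does
(~1e−14°).

What passing these benchmarks shows: the energy, scan, refinement,
pose solver, regression, fusion and metrics are implemented exactly as
specified, with the oracle-equivalence tests pinning the search
arithmetic. What it does not show: performance on real faces. The
generator has no iris texture, eyelashes, gaze-dependent iris
ellipticity, off-axis illumination, compression artifacts, or landmark
detector noise, and the session model has no mapping mismatch (real
gaze-to-screen functions are only approximately polynomial). Published
accuracy on the real benchmarks (98.87% of images at e ≤ 0.05;
5.7°/4.0° mean H/V) depends on those external datasets and is out of
scope here; the shipped error tables are used only to validate the
aggregation arithmetic.

# Numerical choices and degenerate inputs

* Pixel coordinates are 1-based pixel centers (R convention); the
  landmark origin is the image's top-left corner.
* `r = round_half_up(αN)`, clamped to ≥ 1.
* Scan/refinement ties: smallest x; nearest to rough center, then
  row-major. Documented, deterministic.
* Degenerate ROI boxes (x_r ≤ x_l or y_b ≤ y_t) error; boxes exceeding
  the image clip with a warning.
* Collinear pose landmarks (second singular value < 1e−8 of the first)
  error before the solver runs; zero or negative translation depth
  errors at projection.
* Rank-deficient calibration designs error, naming the collinear terms;
  fits require at least as many frames as terms.
* Coincident ground-truth iris centers (d = 0) make the normalized error
  undefined and error out, as does an eyeball coincident with a screen
  point.
* All stochastic draws flow from a single seed per spec object; fixture
  rendering restores the caller's RNG state.

# Problem sizes

The test-suite and the acceptance script run entirely at desk scale,
chosen to exercise every code path with comfortable margins: 200
synthetic ROIs per localization condition, 50 images for oracle
equivalence, a 5×5×3 pose grid, sessions of 40–300 frames (the
function-default calibration length remains 1000, matching the
protocol), and 20 seeds for the fusion comparison. The full suite runs
in well under a minute.

# Limitations

* When the initialized radius underestimates the true iris radius
  (α below the true ratio), `G` develops a plateau — the disk stays
  fully inside the iris over a small neighborhood — and the argmax is
  decided by tie-breaks, costing 1–2 px. The anatomical default avoids
  this for compliant inputs; strongly atypical iris sizes would need a
  per-subject α.
* The centerline scan assumes the iris crosses `y = ⌊M/2⌋` to within δ;
  extreme downward gaze with a drooping lid violates this.
* Euler-angle pose extraction is unambiguous only away from gimbal lock
  (|yaw| → 90°), far outside the tested ±30° range.
* Mapping models are person-specific by design; there is no feature
  normalization across subjects.
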