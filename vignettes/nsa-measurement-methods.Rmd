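---
title: "Measuring the neck-shaft angle of hip resurfacing prostheses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the neck-shaft angle of hip resurfacing prostheses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

After hip resurfacing arthroplasty (HRA), the radiographic neck-shaft angle
(NSA) — the angle between the femoral shaft axis and the axis of the
prosthesis stem sitting in the femoral neck — is a key indicator of implant
positioning. Clinicians measure it on the anterior-posterior (AP)
radiograph with the *trapezoid technique*: the neck (or stem, or shaft) is
treated as a quadrangle, the axis is the line through the midpoints of two
transverse landmark segments, and the NSA is the angle between the neck
axis and the shaft axis, typically near 135 degrees.

`nsavision` automates this measurement. Its pipeline (i) denoises the image
with an edge-preserving bilateral filter, (ii) finds the prosthesis by
exhaustive mean-squared-error (MSE) template matching against a bank of
reference prosthesis images, (iii) takes the femur region to be the area
under the lower side of the detected prosthesis, (iv) extracts straight
edges in both regions with a Hough transform and aggregates each region's
line angles with the median, and (v) reports the NSA as the sum of the
absolute values of the median femur angle and the median prosthesis angle.
A small neural network then *fuses* the AP and lateral NSA measurements
into a corrected AP NSA, trained against clinician ground truth.

Because real postoperative radiographs cannot ship with a package, a
synthetic-radiograph generator with fully known geometry stands in for
them. Every quantitative claim the package's tests make is therefore a
claim about this synthetic family, not about clinical images; the
generator is designed so that each pipeline stage faces the same
*qualitative* challenges it would face on a radiograph (high-contrast
edges, background noise, an implant whose appearance varies in size and
orientation, and two views that disagree).

## Angle conventions

All axis angles are signed degrees measured from the image horizontal,
increasing counter-clockwise on screen, folded to the half-open interval
$(-90, 90]$; a vertical line is $+90$, never $-90$. The shaft is rendered
near-vertical and the stem oblique with the opposite sign, so the NSA
formula
$$\mathrm{NSA} = |\tilde a_f| + |\tilde a_p|,$$
with $\tilde a_f$ and $\tilde a_p$ the median femur and prosthesis line
angles, lands in the anatomical range: a shaft at $+82$ and a stem at
$-53$ give $135$. Under this shared-reference convention the sum of
absolute values equals the geometric angle between the two axes exactly
when the two angles carry opposite signs, which the scene validator
enforces.

One consequence is documented rather than patched: the *median* of signed
angles is discontinuous at the vertical fold. A shaft at exactly $90$
whose detected edges straddle the fold (e.g. $\{+89.8, -89.9\}$) would
yield a nonsensical median near zero. The cohort generator therefore
samples shaft angles in $[78, 88]$ by default, away from the fold, and
this failure mode should be kept in mind for clinical images with a
perfectly vertical shaft.

## The synthetic scene and its ground truth

A scene renders, on a $192 \times 192$ background of intensity 30 (8-bit
scale): a femoral shaft band of width 14 px at intensity 180, and a
prosthesis — a filled hemispherical-cup disc plus a stem rectangle — at
intensity 250, followed by additive Gaussian pixel noise (default
$\sigma = 8$) and clamping to $[0, 255]$. High-contrast piecewise-constant
rendering is deliberate: it matches the assumptions of the bilateral
filter (edges survive, background smooths) and of Canny/Hough edge
extraction. The generator does **not** emulate bone texture, soft tissue,
beam physics, or overlapping anatomy; results on it bound what the
geometry pipeline can do, not what a clinical deployment would achieve.

Each scene also emits the clinician's landmarks: a neck quadrangle (two
transverse segments across the stem) and a transverse segment pair across
the shaft, constructed so that the trapezoid technique recovers the
generating NSA to floating precision. This closes the loop between the
`ground_truth` module and the generator and is tested on 100 scenes at
$10^{-6}$ degrees.

### Cohorts and view-dependent noise

The cohort generator draws, per hip, an anatomical (clinician) NSA
$T \sim U(120, 160)$ — a range bracketing typical postoperative values —
and *independent per-view positioning perturbations*
$\eta_{AP}, \eta_{LAT} \sim N(0, \sigma_v)$ with $\sigma_v = 3.5$ degrees
by default. The AP image is rendered with a projected stem angle
corresponding to $T + \eta_{AP}$ and the lateral one to $T + \eta_{LAT}$.
This models the clinical reality that out-of-plane rotation and limb
positioning perturb each projected angle independently, which is exactly
why a second view carries usable information: each radiograph is an
independent noisy reading of the same anatomical angle. With
$\sigma_v = 3.5$ the raw AP measurement disagrees with the clinician
value by about 2.7 degrees on average — the scale reported for
single-view computer-vision NSA pipelines — and an ideal two-view
combination reduces this by roughly $\sqrt 2$. Hips are grouped into
patients with a mostly-bilateral structure (26 bilateral pairs and 5
singletons per 57 hips), and train/test splitting respects patient
boundaries.

The generator's defaults are the package's study conditions and are not
adjusted per experiment: image size $192^2$, shaft range $[78, 88]$, cup
radius $U(13, 19)$ px, stem length 48 px, pixel noise $\sigma = 8$, view
sigma $3.5$ degrees.

## Preprocessing

The bilateral filter weights each neighbor by the product of a spatial
Gaussian ($\sigma_s = 5$ px) and an intensity Gaussian ($\sigma_c = 50$
intensity units) over a $9 \times 9$ neighborhood, with reflect padding
(avoiding dark-border artifacts that would seed spurious Hough lines).
These defaults are a standard mid-strength setting for 8-bit images; the
output is a convex combination of inputs, so intensities never leave the
input range, flat regions lose variance, and a high-contrast step edge's
half-max crossing does not move by more than a pixel — the three
properties the test suite checks. The intensity Gaussian is evaluated
through a lookup table in 0.25-intensity steps; the quantization is
negligible against $\sigma_c$ and keeps the filter fast.

## Prosthesis detection

Template matching is *exhaustive*: every template, at scales
$\{0.8, 1, 1.25\}$, slides over every window position at stride 1, and
the placement minimizing the raw MSE wins. Ties resolve deterministically
(first position in row-major order, then lower template index, then
smaller scale). The implementation prunes with a coarse pre-pass and a
partial-sum early abort; both are *exact* optimizations — a window is
abandoned only when its accumulated squared error already strictly
exceeds the best complete MSE — and the matcher is tested for bitwise
argmin equality against a brute-force triple loop on small instances.
Intensities are compared raw because the synthetic templates and scenes
share one intensity model; a `normalize` flag switches to zero-mean
comparison for images with different calibration.

The femur region is derived, not detected: same columns as the prosthesis
window, starting at its bottom edge, with height twice the prosthesis
height (clipped to the image). The factor 2 is a finite stand-in for
"the area under the prosthesis" and is exposed in the configuration. For
line extraction the prosthesis window is padded by 6 px on the left,
right, and top so that stem edges clipped by the matched window are not
lost, but by only 2 px at the bottom: the femoral shaft begins just
below the stem base, and a symmetric pad would let shaft edge runs leak
into the prosthesis line set and drag its median.

The template bank grades cup radius and stem orientation together
(small, steep implants through large, shallow ones); the scale sweep
fills in sizes between the bank's radii. This coupling reflects how the
rendered implants co-vary and keeps five templates sufficient.

## Line extraction and the NSA

A Canny edge map (hysteresis thresholds 50/150 on the Sobel magnitude of
the 8-bit image) feeds a Hough accumulator over (radius, angle) with 1 px
and 1 degree resolution. Segments are extracted *progressively*: the
strongest cell above the vote threshold is expanded into the edge pixels
within one radius-resolution of its line, those pixels are linked into
runs (gaps above 3 px split a run), runs at least `min_line_length` long
become segments, and all gathered pixels then retract their votes before
the next cell is considered. The retraction step matters: without it, the
digital staircase of an edge a few degrees off one of the quantized
accumulator angles resurfaces as spurious axis-aligned sub-segments,
which systematically drag the median angle toward 0, 45 or 90 degrees.

Each segment's angle is the principal (total-least-squares) direction of
its pixels, refined once by re-gathering pixels in a corridor aligned
with the fitted direction and restricted to the run's own extent. The
endpoint-to-endpoint direction is *not* used: when a cell's quantized
angle clips the pixel chain asymmetrically, endpoints are biased toward
the cell angle by several degrees, while the principal axis of the
gathered pixels stays on the physical edge. On noiseless scenes the
end-to-end NSA error is below 1.5 degrees; with pixel noise
$\sigma = 10$ the cohort mean absolute error stays well under 3 degrees.

Defaults `min_line_length = 18` and `vote_threshold = 15` sit between
the two structures' edge lengths: long enough to reject chords of the
cup circle — including the runs near its vertical and horizontal tangent
points, which stay collinear for about $\sqrt{8r}$ to
$2\sqrt{2r\rho}$ pixels, some 11-16 px at typical radii — and the short
stem end-caps, but short enough to keep the visible stem edges (about
30 px once the cup covers the stem's distal end, whose votes also split
across two radius cells at 1-degree angular resolution, capping a cell
near 15-20 votes). `tune_hough()` reproduces the grid-tuning workflow — minimizing the
mean absolute NSA error over a tuning subset (30 %, i.e. 17 of 57 hips,
with the remaining 40 reserved for evaluation), with failed scenes
scored at the worst case of 180 degrees and ties resolved toward
stricter parameters.

## Two-view fusion

The fusion model is a fully connected network with 2 inputs (the CV AP
and lateral NSAs), two hidden layers of 128 ReLU units, a sigmoid output,
and full-batch Adam at learning rate $10^{-3}$ for 500 epochs — the
smallest standard recipe that converges on this two-feature problem.
Angles are scaled affinely from $[90, 180]$ degrees onto $[0, 1]$; the
default loss is *binary cross entropy on the scaled target*. BCE for a
continuous target is unusual but well defined — on $[0,1]$ it is a proper
scoring rule minimized at the conditional mean — and it is implemented
literally, with plain squared error available as `loss = "mse"`. Both
losses converge to under 1 degree held-out error on a noiseless identity
task, so nothing in the package's conclusions hinges on the choice.

Records are split 80:20 after a seeded shuffle. Splitting is by
*patient* by default (a bilateral patient's two hips never straddle the
split, avoiding leakage), with per-hip splitting available; with one hip
per patient the split of 57 records is exactly 45 train / 12 test. All
randomness (shuffle and weight initialization) is driven by one seed, so
training is bit-reproducible.

## Evaluation and reliability

Agreement between predicted and clinician NSAs is summarized by
Spearman's $r_s$ (average ranks on ties, large-sample t p-value), the
coefficient of determination computed against truth
($R^2 = 1 - SS_{res}/SS_{tot}$, which penalizes bias, rather than the
squared correlation of a refit line), MAE and MSE. The Kruskal-Wallis H
test (tie-corrected, $\chi^2$ p-value) is exposed for arbitrary group
comparisons; with every value identical H is 0 by convention.

The reliability protocol repeats the whole fusion experiment with the
patient order reshuffled each repetition (seed `base_seed + r`),
re-splitting, re-training, and recomputing held-out metrics for both the
fused predictions and the raw AP measurement. The full protocol uses
1000 repetitions; the package default is 50, which stabilizes the
comparison while keeping a full run around half a minute. On the default
57-hip cohort the fused measurement improves the mean held-out MAE from
about 2.6-2.7 to about 2.0 degrees and raises $r_s$, and the test suite
requires this ordering to hold in at least 18 of 20 replicate seeds of
the protocol.

## Numerical and degenerate-input choices

* Intensities are kept as numeric matrices on the 0-255 scale; PNG I/O
  round-trips 8-bit values exactly.
* A constant region has no edges: line detection returns an empty set and
  the pipeline records the hip as a failure (stage `"angles"`) rather
  than guessing; failed hips never abort the cohort run.
* `match_template()` errors when no template fits the image at any scale;
  a prosthesis touching the bottom row makes the femur region empty and
  errors as "femur undetectable".
* Exact MSE ties in matching resolve to the first placement scanned;
  exact vote ties in the Hough accumulator resolve to the lower angle
  index, then the smaller radius.
* The NSA scale range $[90, 180]$ excludes nothing anatomically
  plausible; records outside it are excluded from training with a
  warning rather than silently clamped.
* Problem sizes in the test suite are the package's study conditions:
  cohorts of 57 hips, 100-scene geometry checks, 50-scene accuracy
  checks, 20 replicate seeds of the 50-repetition reliability protocol.

## Known limitations

* Synthetic scenes are piecewise-constant; nothing here validates
  robustness to texture, soft-tissue gradients, or overlapping anatomy.
* One prosthesis per image is assumed; bilateral hips must arrive as two
  cropped images.
* Matching is not rotation-invariant; orientation variation is covered
  only through the template bank's spread of stem angles.
* The median-of-signed-angles aggregation breaks for perfectly vertical
  shafts (see the convention section).
* The fusion network is trained per cohort; no claim is made that
  weights transfer between cohorts with different error structure.
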