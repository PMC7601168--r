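---
title: "Texture-based screening of oral autofluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based screening of oral autofluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oratex)
```

## The screening problem

Under blue-light excitation, normal oral mucosa fluoresces brightly while
dysplastic and otherwise lesional tissue absorbs the excitation light and
appears dark. Screening devices exploit this, but reading the images —
deciding which dark patch merits a biopsy — still depends on an
experienced clinician. `oratex` automates the first pass: it divides an
autofluorescence image into 64 × 64-pixel super-pixels and classifies each
one as *standard* or *anomalous*, so flagged super-pixels can guide biopsy
site selection.

The pipeline is, in order: optional removal of the imaging device's
circular aperture (edge detection plus a circular Hough transform),
fixed-depth quadtree division into super-pixels, gray-level co-occurrence
matrix (GLCM) texture features per super-pixel, Fisher linear-discriminant
feature ranking, and a k-nearest-neighbour (KNN) classifier evaluated
under grouped cross-validation.

## Coordinates and data types

All rasters are integer matrices with the origin at the top left; indices
are 1-based throughout, the R idiom shared by every imaging package this
one builds on (EBImage, png, tiff). Images are 8-bit (`gray_image`,
intensities 0–255); masks (`label_mask`) are 0/1 with 1 = anomalous, and
any nonzero pixel of a mask file counts as anomalous so that 1-valued and
255-valued mask conventions both work. RGB input is reduced with the
Rec. 601 luminance weights (0.299, 0.587, 0.114), rounded to the nearest
integer — any fixed convention would do, this one is simply the common
default for 8-bit still images and is pinned by tests.

## Edge detection

The gradient is computed with the Deriche recursive filter: a separable
pair of an exponential smoothing kernel `s(x) = k(1 + α|x|)e^{-α|x|}`
(normalised to unit sum) and its antisymmetric derivative
`d(x) = -c·x·e^{-α|x|}`. Both are realised exactly as second-order
recursive filters (causal + anticausal passes sharing poles `2e^{-α}` and
`-e^{-2α}`), so the cost is independent of the effective kernel width
`1/α`. The default `α = 1` px⁻¹ is a middle ground: small enough to
suppress pixel noise, large enough not to displace the aperture rim.
Borders are handled by reflect padding long enough (30/α samples) that the
boundary transient decays below 10⁻⁹ of signal scale.

Edge maps follow the Canny recipe: gradient magnitude, non-maximum
suppression, hysteresis linking under 8-connectivity. Two numerical
choices matter:

* **Interpolated non-maximum suppression.** Comparing each pixel against
  the two neighbours along a 4-sector-quantised direction was implemented
  first, but it measurably over-suppresses oblique ridges: a planted
  circular rim fragmented into ~32 components, with gaps clustered at the
  sector-boundary angles, and the ring pixel count fell ~17% short of
  `2πr`. The shipped implementation therefore compares against magnitudes
  linearly interpolated between the two 8-neighbours bracketing the true
  gradient ray. Rings come out closed (one 8-connected component, count
  within 15% of `2πr`), which is what the circle detector downstream
  needs.
* **Tie-breaking.** With an antisymmetric derivative (`d(0) = 0`) an ideal
  step edge produces an exact two-pixel magnitude plateau. The keep rule
  (`> ` backward neighbour, `>=` forward) retains exactly one pixel of
  such a plateau, so ideal steps yield one-pixel-wide lines.

Hysteresis thresholds default to the 70th/90th percentiles of the nonzero
gradient magnitude. Percentiles adapt to scene contrast, which varies a
lot between device-present (near-black exterior, bright rim) and
device-absent frames; fixed magnitude thresholds would need per-dataset
retuning. Both are exposed (`edge.low_quantile`, `edge.high_quantile`),
as is `edge.alpha`.

## Device-aperture removal

Some frames include the device's circular aperture: a bright rim around
the oral cavity with a near-black border outside. Classifying that region
would be meaningless, so it is detected and removed; frames without a
device pass through untouched, and *absence of a circle is a valid
outcome, not an error*.

Candidate circles are sought over radii 0.30–0.48 of the short image side
(the aperture dominates the frame when present) in steps of 2 px. Voting
is gradient-directed: each edge pixel casts two votes along its gradient
ray (the centre of a circular rim lies on that ray), which sharpens the
accumulator and is far cheaper than isotropic voting over the whole
circumference. Peaks are pooled over 3 × 3 accumulator cells so rounding
does not split them.

Scoring a peak needed care. Raw pooled vote counts saturate (one pixel's
vote circle can graze the pooled peak several times), and counting
supporting pixels — or even arc cells containing *any* supporting pixel —
is defeated by textured lesions: at the study conditions the lesion
interior contributes ~19% edge-pixel density, enough to "support" half of
any large candidate circle. The shipped score is the fraction of ~7-pixel
arc cells of the candidate circumference holding **at least 3 edge pixels
whose gradient is radially aligned within 20°**. A genuine rim traces
every arc cell with radially oriented edges (score ≈ 1; a half-complete
rim ≈ 0.5); isotropic texture speckle rarely aligns (measured false
scores ≤ 0.29 over 30 device-absent scenes). The acceptance floor stays
at `cht.score_floor = 0.35`, which cleanly separates the two populations.
When no gradient fields accompany the edge map (e.g. a synthetic ring
fixture), voting and scoring fall back to the isotropic forms.

An accepted circle blanks everything outside it and crops to the circle's
bounding square (corners zero-filled). The choice of bounding square over
inscribed square keeps the full usable disc; the zero-filled corners are
excluded downstream via a recorded fill mask rather than fed to the
classifier as fake black texture.

## Quadtree super-pixels and the labelling rule

Quadtree subdivision halves each side per level, so subdividing to a
64-pixel leaf is exactly the uniform 64 × 64 tiling; the implementation
tiles directly and the equivalence is pinned against a literal recursive
oracle in the tests. Images whose sides are not multiples of 64 are
zero-padded bottom/right; windows overlapping padding or the
device-removal fill are flagged invalid and never enter training or
testing. A native 1792 × 1792 frame gives the 28 × 28 grid of 784
super-pixels.

A window is labelled **anomalous only if every one of its 4096 pixels is
inside the delineated lesion**; one standard pixel forces the standard
label. The rule is deliberately conservative: a flagged super-pixel lies
wholly within the lesion and is therefore a safe biopsy target. A window
with 4095 of 4096 lesion pixels is still *standard*.

## Texture features

Each valid window yields a co-occurrence matrix over the full 256 gray
levels — no requantisation, because the discriminating texture differences
are subtle and coarser binning averages them away — at displacement
(0, 1): 0°, distance 1. Accumulation is symmetric (each pair counted in
both orders), the original convention, making `p` symmetric with equal
marginals. Other displacements (45°/90°/135°, longer distances) are
supported through the `offset` argument but are not the default.

Ten Haralick features are computed: angular second moment, contrast,
correlation, variance, inverse difference moment, sum average, sum
variance, sum entropy, entropy, difference variance. Conventions, all
exercised against a literal-summation oracle to 10⁻¹⁰ relative error:
natural logarithms with `0·log 0 := 0`; contrast weights `P(|i−j| = n)`
by `n²`; the inverse-difference-moment weight is `1/(1 + (i−j)²)`;
correlation is `(Σ i·j·p(i,j) − μxμy)/(σxσy)`, reported as 0 with a
degenerate flag when a window is constant; variance is taken about the
marginal mean (the two marginal means coincide under symmetric
accumulation); sum variance is taken about the sum entropy; sum entropy
carries the minus sign so it is non-negative. Difference entropy and the
first information measure of correlation are available behind
`extended = TRUE` for users who want that variant of the feature set; the
ten above are the default.

## Feature ranking

Features are ranked by the univariate Fisher separation
`Δ² = (μ₁ − μ₂)² / C`, with `C` the sample-size-weighted pool
`(n₁C₁ + n₂C₂)/(n₁ + n₂)` of the per-class *population* variances —
implemented exactly in that weighting. One scalar per feature, sorted
descending; ties break toward the lower feature index. Δ² is invariant to
affine rescaling of a feature, so ranking is unaffected by the features'
wildly different natural scales. A zero-variance feature with unequal
class means is reported as `+Inf` (ranked first) with a warning. The
multivariate form (`β = C⁻¹(μ₁ − μ₂)`, `Δ² = βᵀ(μ₁ − μ₂)`) is exported
as `lda_model()` and reduces to the univariate score on one feature — a
reduction the tests verify. The default selection depth is the top 8
features, the depth at which classification performance peaks in the
feature-addition sweep (`run_training(..., sweep = TRUE)` reproduces the
whole sweep).

## Classification and evaluation

The classifier is KNN with `k = 1` (configurable) on z-score-standardised
features, Euclidean distance. Standardisation parameters are fitted on the
training fold only; features with zero training variance are dropped with
a warning. Vote ties break toward *anomalous* — missing a lesion is
clinically costlier than flagging a normal region.

Cross-validation is grouped: images are assigned to groups, and within
each group one fold per image trains on the group's other images and
tests on the held-out image, so every image is tested exactly once and a
test image's super-pixels never appear in its own training set (a leakage
property the tests assert directly). Metrics are sensitivity
`TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy over super-pixels,
with anomalous as the positive class; zero-denominator cases are reported
as `NA` ("undefined"), not zero. Reports carry per-fold counts, the
across-fold mean ± sd, and pooled (micro-averaged) metrics over the
summed confusion counts.

## The synthetic-scene generator

No public archive of clinical autofluorescence frames with delineations
exists, so the package carries a seeded generator that reproduces the two
texture statistics the GLCM features respond to:

* **Background** (normal mucosa): Gaussian-smoothed white noise,
  mean 180, sd 5, smoothing scale 4 px — bright and locally smooth, so
  displacement-1 co-occurrences hug the diagonal.
* **Lesions**: mean 60 (absorbing tissue must be darker than background —
  the constructor rejects specs violating this), unsmoothed noise with
  sd 20 (4 × the background sd), i.e. high local contrast at
  displacement 1. Support is a union of `n_blobs = 2` irregular disks
  (low-order Fourier radial deformation, amplitude 0.08) at a target area
  fraction of 0.25. The primary blob takes 60% of the target area and,
  when large enough to contain a full 64-pixel window, is placed roughly
  window-centred (±3 px jitter): clinical lesions span several windows at
  the native 1792-pixel scale, and this placement preserves that property
  at the 256-pixel test scale, guaranteeing at least one fully-lesional
  super-pixel per scene so the benchmark always has a positive class.
* **Device aperture** (optional): exterior filled near-black (intensity
  2), with a 2-px bright rim ending exactly at the aperture radius so the
  strongest edge sits at the true radius.

A generator self-check, asserted in the tests, measures the contrast (f2)
and variance (f4) of fully-lesional windows against lesion-free
background windows: they differ by far more than 3 pooled standard
deviations (≈ 100 and ≈ 70 at the defaults). The comparison deliberately
excludes windows straddling the lesion border: those mix both textures,
are labelled standard by the all-pixels rule, and would dilute a
texture-level measurement.

What the generator does **not** emulate: illumination falloff and
vignetting, specular reflections, anatomy (teeth, tongue dorsum texture),
lesion-subtype appearance differences, motion blur, or inter-device
colour response. Passing the synthetic benchmark therefore demonstrates
that the pipeline machinery — device removal, tiling, features, ranking,
grouped evaluation — is correct and leak-free under the stated texture
model; it does not certify clinical performance, which can only be
measured on clinical images.

## Problem sizes and defaults

The test suite and the acceptance script work at 256-pixel scenes
(16 super-pixels each; benchmark of 10 scenes in 2 groups), a size chosen
so the whole pipeline — including edge detection and the circular Hough
search per image — runs in seconds per scene while exercising every
branch; the 1792-pixel geometry is exercised where it matters, in the
quadtree stage, whose published 28 × 28 grid is asserted directly.
Super-pixel size stays at 64 px at every scene size: texture statistics
per window, not window count, are what the features see.

## Known limitations

* One aperture per frame; ellipse fitting (oblique device angles) is out
  of scope.
* The labelling rule makes boundary super-pixels systematically
  *standard*; sensitivity is therefore defined with respect to
  fully-lesional windows, matching the biopsy-guidance intent, but small
  lesions (under one window) are invisible to the system.
* With `k = 1` and within-group training, each fold's training set is
  small; the protocol mirrors the grouped design it implements rather
  than maximising accuracy. A `global_training` flag trains on all other
  images instead.
* The correlation feature is undefined on constant windows and reported
  as 0 with a flag; downstream ranking treats it like any other value.
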