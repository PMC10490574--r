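---
title: "Methods: segmentation, features and selection for PFB classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, features and selection for PFB classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfbmri)
```

This vignette is the package's own account of its methods: the model each
stage implements, the assumptions behind it, the parameters that matter,
and the places where the design was genuinely open and a choice had to be
made. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Problem setting

Bone mineral density is measured clinically by DEXA; the resulting
T-score separates healthy bone (T > −0.9) from osteopenic or
osteoporotic bone (T ≤ −0.9, pooled here into one "unhealthy" class,
label 1). The package asks how far a routine 2D hip MRI slice can stand
in for DEXA: segment the proximal femoral bone (PFB), describe its
geometry and texture numerically, and classify. The threshold is applied
strictly: a T-score of exactly −0.9 is unhealthy.

Because multi-centre MRI comes from different scanners and protocols
(seven TR/TE/flip-angle settings in the cohort this design mirrors; see
`mri_protocols()`), intensity-based features are expected to travel
poorly across protocols, while geometric features — lengths and angles of
the segmented bone — should be protocol-invariant. That expectation
drives the feature design.

## The synthetic phantom: what it emulates and what it does not

`generate_phantom()` renders a femur-like bright region on a darker
background: a circular head (radius `head_radius_px`), a straight neck of
width `neck_width_px` leaving the shaft at the anatomical neck–shaft
angle, and a vertical shaft. The intensity model is a Gaussian field
inside the bone, a constant background, a global protocol gain, and
salt-and-pepper noise on a fraction of pixels. `phantom_dataset()` draws
cohorts in which the unhealthy class has (scaled by a `separation`
parameter in [0, 1]) a narrower neck, a slightly smaller head, lower and
more variable bone intensity, and a steeper neck–shaft angle — a
caricature of cortical thinning and marrow change. Defaults for the
healthy class are head radius 18–22 px, neck width ~N(15, 1.2) px, angle
~N(130°, 3°) on a 128-px frame (scaled for other sizes), bone mean 180,
SD 8, background 30, 2% salt-and-pepper; at full separation the unhealthy
class shifts by −4.5 px neck width, −40 intensity, +7 SD, +6°. These are
realistic proportions for an adult femoral head/neck at this resolution,
chosen once; `separation = 0` makes the classes identically distributed,
which is the package's null benchmark.

The phantom deliberately does **not** emulate: surrounding anatomy
(acetabulum, muscle, marrow texture gradients), partial-volume effects,
bias fields, or inter-subject pose variation beyond left/right flipping.
Passing tests on phantoms therefore demonstrate that the pipeline's
machinery is correct and parameter-recoverable, not that its clinical
accuracy on real scans matches any published figure.

Gaussian noise injection (`add_gaussian_noise()`) calibrates the noise
variance against the mean squared intensity of the whole image
(`10·log10(P_sig/σ²) = snr_db`). Whole-image signal power is a
convention; an in-mask alternative would raise the effective SNR inside
the bone. Output is clipped at zero to keep intensities physical; the
calibration itself is checked unclipped, because at SNR ≤ 0 dB clipping
truncates much of the background noise and the post-clip variance no
longer measures the calibration arithmetic.

## Segmentation

Both segmenters run on the median-filtered image (5×5, reflection
padding — the classical cure for salt-and-pepper noise).

**Region growing.** Canny edges (Gaussian blur σ = 1.4, Sobel gradients,
non-maximum suppression, hysteresis at the 0.70/0.90 quantiles of the
gradient-magnitude distribution, floored at a small fraction of the peak
so exactly-flat images yield no edges) form barriers; the complement of
the 3×3-dilated edge map is flood-filled (4-connectivity) from the seed.
The flood leaves the region ~1.5 px inside the true boundary (half the
dilated edge band), so the region is re-dilated (3×3 box, then 3×3
diamond) before a 5-px-disc closing and hole filling. The re-dilation
widths were chosen by measuring the boundary deficit on phantoms with
known truth; without them the Dice score is capped around 0.95 by
construction.

Seeding prefers the Hough-circle centre: the femoral head is the dominant
circular structure in a hip slice, so the highest-scoring circle (radius
range defaulting to 15–45% of the smaller image dimension, accumulator
normalised by perimeter and lightly box-smoothed) gives a reliable
in-bone point. If no circle reaches 30% perimeter support, the fallback
seed maximises the row-wise and column-wise intensity sums (ties to the
smaller index).

**Active contour.** A morphological Chan–Vese scheme: a binary level set
initialised as a circle (1.5× the Hough radius), whose interface pixels
join whichever side's mean intensity they are closer to, with a 3×3
majority smoothing per iteration, an iteration cap of 200 and
convergence detection. The region-based energy was chosen over an
edge-based snake deliberately: it is deterministic, parameter-light, and
grows contiguously from the initial circle to cover the whole bright
bone — including the distal shaft, which an edge-attracted snake started
around the head cannot reach. A contour that collapses below 10 px or
floods more than half the image border raises a segmentation-failure
condition rather than returning a mask.

**Choosing between them.** With ground truth, the higher-DSC mask wins
(ties prefer region growing). Without it, a plausibility screen accepts
masks that are a single component, occupy 2–40% of the image, and have
convex-hull solidity ≥ 0.70. The solidity floor is set below the usual
0.85 because an anatomically correct femur mask — head plus oblique neck
plus shaft — has hull solidity around 0.74 by construction; 0.85 would
reject every correct segmentation. If both methods fail, a manual-mask
PNG (the fallback used for the handful of unsegmentable scans in this
kind of cohort) can be supplied.

## Geometric features

The published feature diagram for the 12 geometric quantities is
pictorial, so their operational definitions are this package's
reconstruction, chosen to be scale-equivariant and recoverable from the
phantom generator's parameters:

* **Head**: the largest inscribed circle in the superior part of the
  mask, found at the distance-transform maximum; centre (x₁, y₁),
  diameter W₀.
* **Shaft axis**: principal axis of the inferior third of the mask,
  oriented distally; L₂ is the mask extent along it, W₃/W₄ chord widths
  at the proximal/distal thirds of the inferior segment.
* **Neck axis**: the line through the head centre and the mean midpoint
  of the near-minimal chords along the head-to-junction path. This
  construction exploits a geometric fact: the midpoint of any chord that
  fully crosses a symmetric band lies on the band's centreline
  regardless of the chord's obliquity, so averaging midpoints anchored
  at the head centre converges in a few iterations even when the initial
  axis guess is 20° off. Corner-clipped chords (cut short by the concave
  neck–shaft notch) are rejected by their residual to the current axis
  line before averaging. Simpler estimators were tried and discarded:
  the head-centre-to-centroid line is biased ~15–20° toward the shaft
  (the centroid is mass-weighted), and a junction found by marching up
  the shaft axis is unstable to sub-pixel alignment with the tilted neck
  band.
* **θ**: angle between the neck axis and the distal shaft direction —
  the anatomical neck–shaft convention, ~130° in adults.
* **W₁**: the minimal width perpendicular to the neck axis along that
  path (L₁ = its distance from the head centre, the neck base); W₂ the
  width at the path midpoint, averaged over the three nearest sampled
  chords to damp sub-pixel quantisation.

Masks with no identifiable neck (whole-mask principal elongation < 1.3,
e.g. a disk) are flagged degenerate: θ takes a 90° sentinel and
W₁ = W₂ = W₀.

Widths are measured by marching quarter-pixel steps along sampled chords;
all features are computed in the canonical crop (right femurs mirrored,
bounding box plus a fixed 5-px frame), which makes left/right pairs give
exactly identical features.

## Boundary-distance curves

The crop's row range is split into three equal bands; C1-0/C1-1/C1-2
record the distance from the left crop edge to the first bone pixel per
row of the top/middle/bottom band; C2-0 scans the left half's columns
from the top, C4-0 the right half's columns from the bottom. The band
and direction assignment is fixed in this orientation convention (head
upper-left, shaft lower-right after canonicalisation). Rows or columns
that never meet the mask are dropped; a curve with fewer than 8 raw
samples raises a degenerate-curve error; every curve is linearly
resampled to length 64 so crops of different sizes are comparable.

Curve statistics follow two menus: the bottom band C1-2 (which crosses
the shaft almost perpendicularly and is nearly trend-free) gets plain
signal statistics (min, max, mean, variance, kurtosis, skew, first and
second central moments); the other four curves get the ramp features —
average ramp (the OLS slope: the natural "trend" definition given that
the ramp-removed signal is defined by subtracting it), first-to-last
point ramp (literal endpoints), and the kurtosis/skew/moments of the
ramp-removed signal — plus variance and the maximum discrete second
derivative. "Ramp removal" subtracts the slope component index-wise
(`values[i] − slope·i`): subtracting the scalar slope itself would shift
the curve, not detrend it, and would leave skew/kurtosis of sloped curves
meaningless. Moment conventions are population (biased) throughout, with
excess kurtosis; the first central moment is identically zero and is kept
as a feature slot for layout fidelity — standardisation maps such
zero-variance columns to zero. "Elongation" in the prose tradition of
such feature lists is treated as synonymous with kurtosis.

## Texture features

Intensity mean/variance/skew are computed over in-mask pixels only (the
gray-level mean proxies marrow fat and hence density on T1 images). The
box-counting fractal dimension is computed on the boundary pixel set —
it is used as a boundary-complexity descriptor — at dyadic box sizes
(2, 4, ..., capped at a quarter of the set extent; at least three
scales), as minus the OLS slope of log N(s) against log s. The GLCM
uses 32 quantisation levels over the in-mask range, distance 1, the
symmetric normalised matrix averaged over angles {0°, 45°, 90°, 135°},
with pairs counted only when both pixels are in-mask, summarised by the
canonical quartet contrast / correlation / energy / homogeneity (the
quartet exposed by the mainstream GLCM tooling this family of pipelines
is usually built with). Degenerate (constant) regions return
(0, 1, 1, 1) with a flag.

## Feature assembly and scaling

The 68 primaries are ordered: 12 geometric, 10 C1-1, 8 C1-2, 10 C1-0,
10 C2-0, 10 C4-0, 3 intensity, 1 fractal, 4 GLCM; the vector is extended
by element-wise squares and cubes to 204 entries named `(name)^2`,
`(name)^3`. Powers are the only derived transform. Because the features
mix pixels, degrees and unit-free quantities, kernel classifiers need a
common scale: features are z-scored with mean/SD estimated on the
training rows only (zero-SD features map to 0), inside every
cross-validation fold. Scaling is an addition this package makes
explicit; it changes nothing for scale-invariant learners and is
essential for the SVMs.

## Cross-validation, augmentation, metrics

`kfold_split()` deals class-shuffled indices cyclically with a running
counter across classes, so per-class counts per fold differ by at most
one *and* total fold sizes differ by at most one (for 284 subjects and
k = 10: sizes 28 and 29). Minority-class augmentation — uniform random
rotation in ±40° and horizontal/vertical shifts up to 20% of the image
dimension, applied to images and masks, until class counts are equal —
is available fold-internally: synthetic copies are created only from
training-fold images, never test folds, to avoid leakage. The shift
magnitude is read as a fraction 0.2 of the image dimension, the standard
augmentation convention; a literal 0.2% would be sub-pixel and inert.

Predictions are pooled over folds into one confusion matrix in the
TH/FH/TU/FU naming (healthy = label 0; FH — an unhealthy subject called
healthy — is the clinically costly error). Metrics are accuracy and
macro-averaged F1 in percent, rounded to two decimals for report parity.
Macro-F1 (the mean of healthy-as-positive and unhealthy-as-positive F1)
is adopted because it exactly reproduces the published F1 values from
their printed confusion matrices for all six classifier rows — verified
arithmetically in the test suite.

Classifier defaults: SVM cost 1; polynomial degree 3 with coef0 = 1; RBF
kernel scale 1/(d·mean variance), Gaussian kernel bandwidth from the
median pairwise distance (the two radial rows of such comparisons differ
by kernel-scale policy, and this is the reconstruction adopted here);
decision tree with Gini splits and cp = 0.01; logistic regression as an
unpenalised GLM fit (via `glm.fit` for speed). All are exposed through
`classifier_spec(...)`.

## Genetic-algorithm feature selection

Chromosomes are bitmasks over the feature columns; the cost
1/(Accuracy + 1/NOF) is minimised, with Accuracy a fraction in [0, 1].
Treating accuracy as percent would make the 1/NOF term negligible and
remove the pressure toward few features that the cost is designed to
exert. Operators (unspecified in the tradition this follows, so fixed
here as standard defaults, all configurable): tournament selection of
size 3, uniform crossover with probability 0.8, per-bit mutation at
1/n_bits, elitism of one, empty chromosomes repaired by switching one
random bit on. Fold assignment is fixed per run so all chromosome costs
are comparable, and evaluations are cached by bitstring — fitness
evaluation dominates runtime. Elitism makes the best-cost series
monotone non-increasing, asserted on every run. The per-iteration best
chromosomes are retained so `selection_map()` can render the
feature-by-iteration selection raster (steadily chosen features appear
as solid horizontal lines). Reference settings are population 100 with
500 iterations; the planted-feature benchmark in the tests uses
population 40 and 40 iterations, which recovers the exhaustively
certified singleton optimum in all tested seeds.

## Numerical choices and degenerate inputs

* Coordinates are (row, col), 1-based in R, row 1 at the top; masks use
  the 0/255 PNG convention on disk.
* Chord marching uses 0.25-px steps and nearest-pixel membership tests;
  curve resampling is linear interpolation to length 64.
* Zero-variance signals (flat curves, constant regions) return zeroed
  shape statistics with a degenerate flag rather than NaN; assembly
  rejects non-finite features by name.
* Every stochastic operation takes an explicit integer seed and restores
  the caller's RNG state; identical seeds give bit-identical phantoms,
  folds, GA runs and pipeline outputs.
* Error conditions are classed (`pfbmri_seed_error`,
  `pfbmri_seg_failure`, ...) so callers can distinguish failure modes
  programmatically; `segment_best()` aggregates both methods' failure
  reasons into its error message.

## Problem sizes used in the checks

The automated checks run on deliberately modest sizes chosen to exercise
the estimators' operating ranges: 96–256-px phantoms; 30 phantoms for
parameter recovery; 200 subjects for the null-classification band (at
chance level, a pooled accuracy over 200 subjects has a standard error
of ~3.5%, so the 40–60% acceptance band is a ~3σ test); 60 subjects with
full segmentation for the separable benchmark; 10 GA seeds on the
21-feature planted benchmark. These are the package's reference
conditions; all scale up by arguments.

## Known limitations

* The geometric definitions are reconstructions; a different reading of
  the pictorial feature diagram would relabel some widths without
  changing the pipeline's mechanics.
* The neck-axis estimator assumes one head, one neck, one shaft in
  roughly canonical orientation; pathological anatomy or failed
  segmentations fall back to the degenerate flag rather than recovering.
* Phantom benchmarks bound machinery correctness, not clinical
  performance; the phantom's texture model is far simpler than trabecular
  bone.
* The noise sweep re-segments noisy images but reuses the clean mask when
  segmentation fails outright at very low SNR (counted and reported), so
  accuracies below ~0 dB partially reflect feature robustness rather than
  segmentation robustness.
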