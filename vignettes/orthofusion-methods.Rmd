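---
title: "orthofusion: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthofusion: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what each stage
computes, the assumptions behind it, the numerical conventions that matter
for reproducibility, and the choices we made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The decision problem

The package targets the binary extraction / non-extraction treatment
decision in orthodontics, approached as a supervised classification problem
over features extracted from two imaging modalities: 3D intraoral scans of
the dental arches (IOS) and 2D lateral cephalometric radiographs (LCR).
The positive class throughout is *extraction*; cohorts are imbalanced, with
roughly 31 % positives, and all rates, splits and the F1 objective are
defined with respect to that positive class.

## Arch geometry (IOS features)

An arch is a set of per-tooth 3D centroids keyed by FDI code (14 teeth,
second molar to second molar). When a labelled triangle mesh is the input,
`archFromMesh()` reduces it first: each tooth centroid is the area-weighted
mean of its faces' centroids, which makes the result insensitive to mesh
tessellation density — this is also why the optional vertex-clustering
decimation utility (`decimateMesh()`, default target 16,000 faces) does not
participate in the feature mathematics.

`normalizeArch()` puts an arch into a canonical anatomical frame: the
best-fit (total-least-squares) plane of the centroids becomes Z = 0, the
in-plane direction from the second-molar midpoint towards the
central-incisor midpoint becomes +Y, the left-to-right molar direction +X,
and the right-handed frame is completed by their cross product. The
transform is rigid by construction (pairwise distances preserved to
1e-9 mm), so every downstream feature is invariant to how the scan happened
to be posed. One subtlety: the canonical origin is defined as the
*projection* of the central-incisor midpoint onto the best-fit plane. The
two natural requirements — plane to Z = 0 and incisor midpoint to the
origin — conflict whenever the midpoint sits slightly off-plane, and
projecting resolves the conflict while keeping both properties to within
the midpoint's own off-plane offset.

The four standard measurements follow their clinical definitions on
centroids: inter-canine and inter-molar widths are straight-line distances
between the left/right canine and first-molar centroids; arch depth is the
perpendicular distance from the central-incisor contact midpoint to the
line through the two second-molar centroids; arch length is the polyline
length through all centroids in anatomical walking order. Centroids rather
than cusp tips, and the second-molar line for depth, are deliberate
conventions: they need no landmarking beyond segmentation and they are
consistent with the Bézier anchoring below.

The two per-tooth features are distances (i) to the **arch center**,
defined as the unweighted mean of the tooth centroids — the simplest
rotation-invariant choice, since no more specific definition is standard —
and (ii) to a **quadratic Bézier curve** through the arch. The curve is
anchored at the second-molar centroids (p0, p2) with the middle control
point chosen in closed form, `p1 = 2M − (p0 + p2)/2`, so that the curve
interpolates the central-incisor midpoint M exactly at `t = ½`. This is
the unique quadratic through the three anatomical anchors with the
symmetric parameterisation. Distances are computed in 3D after
normalisation (not projected into the occlusal plane); projecting is a
one-line change but discards vertical displacement information.

Point-to-curve distance is computed by dense sampling of `t ∈ [0,1]`
(257 points) followed by local refinement (golden-section, `stats::optimize`)
of *every* sampled local minimum. The squared distance to a quadratic curve
is a quartic in `t` with at most three interior critical points, so
refining all sampled minima cannot miss the global one; the tests verify
agreement with both a closed-form cubic-root oracle and a 10⁶-point grid to
within twice the requested tolerance (default 1e-6 mm).

The subject-level IOS vector concatenates, per arch (maxilla then
mandible): the 4 measurements, the 14 center distances and the 14 Bézier
distances in anatomical order — 32 per arch, 64 per subject, with stable
column names (`mx_arch_length`, `md_ctr_dist_31`, ...). Maxilla and
mandible are concatenated rather than pooled so that arch-specific
asymmetries remain visible to the classifier.

## Cephalogram standardisation

`standardizeCeph()` applies, in order: global 256-bin histogram
equalisation (the common global variant; CLAHE was considered but a
configurable global equalisation is the reproducible default), symmetric
zero-padding to square, and bicubic resize to 240×240 with intensities in
[0,1]. Two conventions are fixed and recorded because they affect exact
bounding-box inversion:

* odd padding remainders go to the bottom/right;
* the bicubic kernel is Catmull–Rom (a = −0.5) with clamped borders and
  half-pixel-centre alignment — bicubic dialects differ across imaging
  stacks, so the kernel is implemented explicitly in `resizeBicubic()`
  rather than left to a library default.

The padding/scale record is stored in the image metadata;
`unprojectBbox()` maps a detector-space box back to original coordinates
(scale by `square_side/240`, subtract the pads, clip to the image) and is
the exact inverse of `projectBbox()` on boxes inside the content region.
The trained region-of-interest detector itself is out of scope: boxes are
supplied per image (CSV), with `heuristicBbox()` (bounding box of
high-gradient pixels) available as an explicitly non-equivalent fallback.
`cropResize()` then crops the original grayscale image and resizes to
256×256.

`augmentImage()` provides the training-time corruption chain: a random
similarity transform (rotation, translation, zoom; bilinear resampling,
zero background), Gaussian noise, and aggressive masking that zeroes random
16×16 patches until the requested pixel fraction is occluded. The chain is
deterministic given its seed, is the exact identity when all parameters are
zero, and is intended for training folds only — held-out images must never
be augmented.

## Pairwise landmark angles (Land features)

For 29 ordered landmark coordinates, the feature is the orientation angle
of every unordered pair: for `i < j`, `atan2(y_j − y_i, x_j − x_i)`,
concatenated in lexicographic pair order — C(29,2) = 406 values in
(−π, π]. We use the two-argument arctangent because the single-argument
arctangent of the slope is undefined for vertical pairs; a configuration
switch (`convention = "undirected"`) folds angles modulo π for the
line-orientation reading. The representation is exactly invariant to
translation and uniform scaling, and a global rotation shifts every angle
by the same amount (verified to 1e-9 in the tests); it is therefore a
purely relational encoding of the landmark configuration. Landmark order is
taken from the input file; no anatomical naming is imposed.

## The attention autoencoder (AE features)

The autoencoder is fully convolutional — no fully connected layers anywhere
— so the latent representation stays spatially structured. The encoder has
three 3×3 stride-2 convolution stages with 32, 64 and 128 filters (ReLU),
each followed by a spatial-attention gate; a 1×1 convolution then reduces
the 32×32×128 map to a 32×32×4 latent embedding. The decoder mirrors the
encoder with three stride-2 transposed convolutions (4×4 kernels, which
give exact 2× upsampling without output padding) and a logistic output in
[0,1].

The attention gate is one reasonable concretisation of "spatial attention"
(no formula is standard): per position, the channel-wise mean and maximum
form a 2-channel summary, a 7×7 convolution maps it to a single logit, and
a logistic squashing yields a multiplicative map in [0,1] applied to every
channel at that position. The gate is the identity when saturated at 1,
which the tests assert directly.

Training minimises mean-squared reconstruction error (the conventional
choice for grayscale reconstruction) with Adam (lr 1e-3), seeded He
initialisation and a seeded shuffle, so two runs with the same
configuration produce bit-identical loss traces. The whole engine is
implemented in plain R as offset-wise BLAS matrix products (a stride-2 3×3
convolution is nine gathered matrix multiplications; the transposed
convolution is the adjoint scatter of the same geometry), and the backward
pass is verified against finite differences in development. The training
contract asserted by the tests is deliberately modest: the final dataset
loss must fall below the loss before any update, and descriptors must move
— reconstruction *quality* on real radiographs is explicitly not a claim.

Descriptors come from spatial pyramid pooling of the latent map: grids
[1×1], [2×2], [4×4], [8×8] partition the map into 85 regions, each pooled
per channel (max by default, the classical choice; mean by option),
concatenated coarse→fine, cells row-major, channels fastest — 85 × 4 = 340
values regardless of latent size. The input side length is configurable
(any multiple of 8; 256 is the study resolution). The package's tests train
at 64 px with ≤ 8 images and ≤ 3 epochs — the contracts under test
(shapes, determinism, loss decrease, pooling arithmetic) are
size-independent — while architecture shapes are asserted at the full
256 px.

## Fusion, tuning and the ensemble

`stratifiedSplit()` reserves `ceiling(n × fraction)` subjects for testing,
with the minority class contributing the floor of its proportional share;
these rounding rules are fixed so that a 617-subject cohort with 192
positives yields the canonical 493/124 partition with 38 positive and 86
negative test subjects.

Each feature group is preprocessed independently — Z-score scaling, then
PCA keeping the smallest component count reaching 95 % cumulative
explained variance; zero-variance features are dropped with a warning —
and the components are concatenated. PCA can be switched off per group
(the main motivation for PCA is the 406- and 340-dimensional LCR groups;
the 64 IOS features barely need it), but the default applies it uniformly.
Crucially, all preprocessing is fitted strictly on the training subjects of
the fold at hand; the fold models save their scaler and rotation, and the
test suite audits that the saved statistics equal statistics recomputed
from the training ids alone.

Model selection uses nested cross-validation: 5 stratified outer folds for
generalisation assessment, 10 stratified inner folds for tuning, and a
Bayesian optimiser spending 100 evaluations (default) per outer fold on
mean inner-fold F1 of the positive class. The optimiser is a seeded
Gaussian-process surrogate (squared-exponential kernel on the unit cube,
fixed length-scale 0.25, standardised responses) with expected-improvement
acquisition over random candidates, initialised by a Latin hypercube; a
pure random search with the same budget sits behind
`optimizer = "random"`. Four families are supported with the following
spaces (chosen as the conventional ranges; none are standard-defined):
ridge-logistic (λ log-uniform 1e-4..1e2), SVC (C log-uniform 1e-3..1e3,
RBF width log-uniform 1e-4..1e1, kernel ∈ {RBF, linear}), random forest
(ntree 100..500, mtry fraction 0.1..0.9, nodesize 1..10) and decision tree
(cp log-uniform 1e-4..0.1, maxdepth 2..10, minsplit 5..40).

Class imbalance is handled by seeded random oversampling of the minority
class to parity, applied only to the classifier-fitting rows inside
training folds — never to validation or held-out subjects (the tests audit
this by id). The best configuration per outer fold is refit on the full
outer-training fold; the five fold models form the deployable ensemble,
which predicts by majority vote of hard labels (five voters, so no ties;
probability calibration is deliberately not used).

## Evaluation

`metricsFromCM()` computes the eight diagnostic metrics; LR⁺ =
sens/(1−spec) and LR⁻ = (1−sens)/spec are reported as `Inf` when their
denominators vanish. `solveCMFromMetrics()` exhaustively searches the
(n_pos+1)×(n_neg+1) grid of integer confusion matrices for those whose
accuracy/sensitivity/specificity round — half-up, 2 decimals, the
convention of printed performance tables (`roundHalfUp()`) — to given
values, with further printed metrics as disambiguators; this is how the
package reconstructs worked examples from published-style tables.

`mcnemarPaired()` compares two classifiers on the same subjects through
their discordant counts b and c: for b + c < 25 the exact two-sided
binomial p-value `min(1, 2·P(X ≤ min(b,c)))`, X ~ Bin(b+c, ½); otherwise
the continuity-corrected chi-square `(|b−c|−1)²/(b+c)` on 1 df. The
threshold 25 is the usual small-sample rule and is configurable, and both
branches can be forced — which variant a given publication used is rarely
stated, so both are first-class. `compareModels()` runs all model pairs on
three criteria — accuracy on all subjects, sensitivity on true-positive
subjects only, specificity on true-negative subjects only (the
conditioning required for a *paired* test) — with significance stars at
0.05/0.01/0.001.

## The synthetic cohort generator

`generateCohort()` exists because cohorts of this kind are private: it
emulates the *structure* of the study inputs well enough to exercise every
pipeline contract, without claiming to estimate any real population.

* **Labels**: exactly `round-half-up(n × fraction)` positives (default
  fraction 0.311, the study's class ratio), assigned by a seeded shuffle.
* **Arches**: tooth centroids at fixed arc-length fractions (derived from
  typical mesiodistal crown widths) of a symmetric parabola in the
  occlusal plane — half-width 27 mm / depth 42 mm for the maxilla, 25/39
  for the mandible; extraction-class subjects have a random subset of
  anterior teeth (incisors and canines) displaced off-curve along the
  local normal by `arch_effect`; all centroids get isotropic Gaussian
  noise, and the whole arch a random rigid motion (which the
  normalisation must undo — a free integration test).
* **Landmarks**: a fixed 29-point template (cranial-vault arc, facial
  profile, mandibular border) with the mandibular points shifted by
  `landmark_effect` in the extraction class, plus isotropic noise and a
  random similarity transform.
* **Images**: procedural grayscale fields — smooth background plus
  Gaussian-profile curves traced through the subject's landmark groups.
  They exercise the preprocessing and autoencoder *contracts*; they are
  not anatomically realistic and were never meant to be.

One global seed fans out to per-subject, per-component substreams, so a
given subject is bit-reproducible independent of cohort size or of which
components are requested.

Default effect scales were fixed once on clinical plausibility — 1.5 mm
crowding displacement against 0.5 mm centroid noise, 5 px landmark shift
against 2 px landmark noise — because the source material gives no feature
distributions to estimate them from. Tests use two regimes on purpose: a
*strong* regime (4 mm effect, 0.3 mm noise) where a competent pipeline must
exceed 0.9 F1, and a *zero* regime where per-class distributions are
exchangeable and nested-CV F1 must sit inside a 20-permutation null band
(mean ± 4 sd). Passing these shows the pipeline learns planted geometric
signal and does not hallucinate signal from noise; it says nothing about
accuracy on real patients, which depends on effect sizes no synthetic
generator can supply.

## Problem sizes and numerical conventions

The test suite and acceptance script run at deliberately desk-scale sizes,
chosen once: cohorts of 80–120 subjects for nested-CV properties (with the
optimiser budget reduced to 10 trials), 617 subjects where the split
arithmetic itself is under test, autoencoder training at 64 px on ≤ 8
images, and 20 label permutations for the null band. Bézier tolerances are
1e-6 mm in geometry tests and 1e-4–1e-3 mm inside cohort-scale feature
extraction (the distance refinement dominates runtime there and feature
differences at those scales are far below the noise floor).

Degenerate inputs are errors, not guesses: collinear arches, missing
required teeth (reported by FDI code), coincident landmark pairs (reported
by index pair), empty crops, non-divisible pyramid levels, folds that lose
a class under stratification.

## Known limitations

* The tooth-segmentation and landmark-detection networks that would
  produce the package's inputs from raw scans/radiographs are out of
  scope; the package consumes segmented arches and landmark tables.
* The autoencoder engine is pure R: correct and deterministic, but not
  fast — full-scale training (hundreds of 256 px images, many epochs) is
  feasible but slow; the design favours auditability over throughput.
* Real-data performance figures cannot be reproduced here (the underlying
  cohort is private); the evaluation module instead reconstructs printed
  diagnostic rows exactly from their integer confusion matrices.
* The attention formula and several hyperparameter ranges are documented
  interpretations of under-specified design points; all are configurable.
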