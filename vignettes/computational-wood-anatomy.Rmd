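---
title: "Computational wood anatomy with xylovision: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational wood anatomy with xylovision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Hardwood species leave a quantitative fingerprint in transverse section: the
sizes of vessel lumens (pores), their arrangement (ring-porous,
diffuse-porous, radial-porous), wall thickness and ray layout.  `xylovision`
implements a classical computer-vision pipeline for species-level
identification from low-magnification transverse-section micrographs and
for exploring how the computed features relate to anatomy:

1. **Pretreatment** — centre square crop, 8-bit grayscale conversion,
   stepwise bilinear downscaling (`crop_square()`, `to_gray8()`,
   `downscale_stepwise()`).
2. **Shape features** — SIFT keypoints (difference-of-Gaussian extrema,
   128-value gradient-orientation descriptors) aggregated per image into a
   mean descriptor, the *bag feature* (`detect_keypoints()`,
   `aggregate_descriptors()`).
3. **Size features** — binarisation at a fixed threshold, 4-connected
   component labelling of the bright lumens, and a log-log histogram of
   `log10(sqrt(area))` with bin width 0.1 (`pore_components()`,
   `histogram_features()`).
4. **Reduction and learning** — Fisher linear discriminant projection to
   `C - 1` dimensions, classification with k-NN (k = 9), multinomial
   logistic regression and a linear SVM under stratified 1:4 train/test
   splits repeated 10 times, and Ward hierarchical clustering
   (`lda_reduce()`, `evaluate()`, `ward_cluster()`).
5. **Keypoint atlas** — k-means (k = 18) clustering of pooled descriptors
   into visual words, Ward subgrouping of the 18 centroids into 5 families,
   per-species composition ratios and keypoint overlays (`build_atlas()`,
   `composition_ratios()`, `overlay_cluster()`).

Because the micrograph collections such pipelines are tuned on are rarely
redistributable, the package ships a first-class synthetic generator
(`generate_micrograph()`, `default_dataset()`) whose ground truth makes
every stage testable.

# The synthetic world

A `porosity_profile()` states one wood class: a Gaussian mixture of pore
diameters (micrometres), an arrangement, a pore density, wall/lumen gray
levels, ray density and pixel noise.  The defaults were chosen once, from
what a wood anatomist would call realistic for a temperate hardwood family,
and are **not** tuned against test outcomes:

* pore diameters span roughly 5–400 µm across the 18 default classes;
  earlywood vessels of the ring-porous classes sit at 200–340 µm, latewood
  and diffuse/radial vessels at 14–110 µm;
* densities are 16–130 pores/mm²;
* lumens render at gray ~224–244 and walls at ~110–135, so the fixed
  binarisation threshold 180 cleanly separates the phases: with the default
  noise (sd 10 gray levels) both phases sit ≥ 4.2 standard deviations from
  the threshold;
* uniseriate rays are thin bright lines (wall + 25) with dark flanks
  (wall − 25), deliberately *below* the binarisation threshold: rays feed
  the gradient-based shape features without polluting the pore census;
* the default scale is 0.74 µm/pixel, the resolution of a 2× objective on
  a standard CCD; the benchmark dataset (`default_dataset()`) generates
  600 × 600 px images directly at 4.44 µm/px = 0.74 × 3600/600, i.e. the
  same 2.66 mm field of view a 3600-px micrograph has after the stepwise
  reduction to 600 px.  Rendering at the working size keeps the benchmark
  inside a test-suite time budget; the full-resolution path is exercised
  separately by the resize ladder's own tests.

Pores are filled ellipses with axis ratio ≤ 1.3 (vessel outlines are nearly
circular), placed without overlap by rejection sampling (1000 attempts,
larger pores first, failures skipped).  The ground truth records only
rendered pores, so mask and areas always agree with an independent
flood-fill of the mask.  In ring mode, mixture components with mean
diameter ≥ 100 µm (`earlywood_min_diameter`) are confined to a band of
width `earlywood_fraction × ring_period` recurring with the ring period;
in radial mode pores share exact column coordinates within radial files
spaced about four mean diameters apart.

Two default classes form a **designed confound**: `cerris_like`
(ring-porous) shares its latewood pore mixture (18 ± 3 µm), contrast and
ray layout with `ilex_like` (radial-porous)'s whole-section mixture, differing only
by the added earlywood band — the synthetic analogue of the classical
similarity between the Cerris and Ilex oak groups, whose latewood/whole
sections match in both element shape and size.  The acceptance suite checks
that the pore-histogram dendrogram reunites this pair.

What the generator does **not** emulate: tyloses and cell contents, growth
ring curvature, stain variation, vessel multiples, and the continuum of
fibre/parenchyma lumens that make real binarisation messy ("filled-in small
lumens, missed thin walls").  A green synthetic benchmark therefore
establishes that the pipeline recovers class structure *of the stated
kind*; it does not certify field accuracy on real micrographs.

# Numerical choices

* **Binarisation** uses strict `intensity > threshold` (lumens are the
  bright phase); the default 180 is the empirical value for
  transmitted-light sections with this contrast convention.
* **Histogram**: sizes are `sqrt(area)` in µm (a pixel-unit mode exists for
  scale-free replication); logarithms are base 10; bins are half-open
  `[edge, edge + 0.1)` on the fixed global range `[0, 3)` (30 bins), so
  vectors align across images.  Counts are stored as `log10(count + 1)`,
  which maps empty bins to 0 and keeps the count recoverable; out-of-range
  components are counted separately and excluded.  Border-touching
  components are retained — excluding them would bias against large
  earlywood vessels.
* **SIFT** follows the reference formulation: initial 2× upsampling, base
  σ = 1.6, 3 layers per octave, contrast threshold 0.06 (checked as
  |DoG| × layers on a [0, 1] intensity scale), edge threshold 10, one
  keypoint per dominant orientation (80% rule), 4×4×8 descriptor with
  trilinear binning, 0.2 clamp and renormalisation.  Descriptors are kept
  as unit-norm floats (the integer-quantised convention of some stock
  implementations is deliberately not reproduced); tests assert the
  structural contract (layout, invariances, monotonicity), not bit-exact
  values.  Images with zero keypoints are dropped from feature tables with
  a warning: a zero vector is not a mean and would distort the
  discriminant geometry.
* **LDA**: within-class scatter is whitened by Cholesky factorisation;
  if it is singular or ill-conditioned a small ridge
  (`1e-4 × mean diagonal`) is added and reported.  Axes are scaled to unit
  pooled within-class covariance, the convention of mainstream
  implementations, so classifier inputs have O(1) scale.  The output
  dimension is `min(C - 1, p)`; with the package's feature types (30 bins,
  128 descriptor dimensions) this is always `C - 1` — 17 for 18 classes.
* **Classifiers**: k-NN uses Euclidean distance, uniform votes, distance
  ties broken by smallest training index and vote ties by smallest class
  index.  Logistic regression is glmnet ridge (α = 0) at λ = 1/n — the
  same penalty as the common default "C = 1" — fitted along a warm-started
  path because multinomial ridge fits at an isolated small λ do not
  converge reliably.  The linear SVM is one-vs-rest dual coordinate
  descent (C = 1) with a regularised intercept.
* **Splits** are stratified per class by default (guaranteeing every class
  in training, as plain random splits cannot); a plain-random mode and a
  group-aware mode (specimens never straddle train/test) exist but are off
  by default.  `lda_scope = "fold"` (default) fits the projection on the
  training portion only; `"global"` reproduces the classical feed-forward
  order (reduce first, then split).  Both are reported in the package's
  own benchmarks; fold-scope is the honest default because global scope
  leaks test information into the projection.
* **Ward clustering** is `hclust(method = "ward.D2")` on Euclidean
  distances — the convention whose merge heights equal
  `sqrt(2 × ΔESS)` — verified against an exhaustive O(n³) implementation
  of the definition.  Dendrograms export to Newick with merge-height
  increments as branch lengths.
* **k-means** uses k-means++ seeding with 10 restarts under an explicit
  seed, Lloyd iterations, and re-seeds empty clusters by splitting the
  largest cluster at its farthest member (reported via a message).  An
  optional `max_pool` cap subsamples the pool uniformly, mirroring the
  memory-limited keypoint studies that restrict the atlas to a species
  subset.

# Open design points, resolved

* The "stepwise" downscaling schedule is not uniquely defined anywhere; the
  default ladder {3600, 1800, 900, 720, 600, 450, 360, 225, 112} (truncated
  to the source/target) includes every side length used by the resolution
  sweep while keeping each hop ≤ 2×, and is fully configurable.  Each hop
  re-quantises to 8 bits, mimicking pipelines that store 8-bit
  intermediates.
* The crop anchor is centred — unbiased with respect to growth-ring
  position.
* Whether component sizes were binned in pixels or micrometres is
  ambiguous in this family of pipelines; the default is micrometres via
  the image scale (resolution-consistent), with `units = "px"` available.
* Ring widths vary across real species and some fields of view contain no
  complete ring; `ring_period` is an explicit profile parameter so both
  regimes can be generated.
* The chance-level acceptance band uses the binomial standard deviation of
  a single repeat's test fraction (n = 108 predictions for the benchmark),
  not of the pooled repeats, because repeated splits of one dataset are
  positively correlated; this is the conservative choice.

# Known limitations

* SIFT here is a faithful re-implementation, not a bit-exact clone of any
  stock library; keypoint counts differ from other implementations by a
  few percent on textured images.
* The linear SVM uses a regularised intercept (the LIBLINEAR bias trick),
  which differs negligibly from an unregularised intercept at these data
  scales.
* `downscale_stepwise()` drops ground-truth masks: label images do not
  survive resampling meaningfully.
* The synthetic benchmark is easier than the real task; its headline
  accuracies (see `scripts/acceptance.R`) are scaled-down analogues, not
  reproductions, of accuracies measurable only on the original
  (undeposited) micrograph collection.
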