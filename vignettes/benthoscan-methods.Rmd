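---
title: "Methods: automated seafloor classification from towed-camera imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated seafloor classification from towed-camera imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(benthoscan)
```

# The problem

Towed camera platforms (OFOS-style frames, ROVs, AUVs) photograph the deep
seafloor every few seconds while moving at about half a knot, producing tens
of thousands of images per expedition. Turning these into substrate or
habitat maps requires (i) a physical scale for each image, because the
camera altitude — and with it the seabed area per frame — varies between
roughly 1 and 4 m; (ii) photometric normalization, because scene brightness
falls with altitude and light falls off radially from the centered lamps;
and (iii) a classifier that can be trained with very little manual labeling,
because expert annotation of forty thousand images is not feasible.
benthoscan implements this workflow end to end for seabeds where the
discriminating objects are manganese nodules: dark, irregular blobs on
light sediment, categorized into four classes (A: bare/turned-over
sediment with few nodules, B: partial nodule patches, C: dense nodule
cover, D: large nodules).

# Scale from laser points

Three lasers with a fixed real-world spacing of $d = 40$ cm project a
triangle of red dots near the image center. The laser signal image is the
channel combination $I^{(LS)} = I^{(R)} - c\,(I^{(B)} + I^{(G)})$ with
$c = 0.2$, computed in signed arithmetic. Local maxima of $I^{(LS)}$ are
thinned to a minimum mutual separation, filtered to a triangular search
mask built from a single hand-annotated image (dilated by a buffer, 250 px
at full resolution), and the top three surviving peaks are refined to
sub-pixel precision by a signal-weighted centroid. The image scale is

$$ s = \frac{\overline{d_{ij}}}{40\ \mathrm{cm}} \quad [\mathrm{px/cm}], $$

the mean pairwise pixel distance of the detected points over the known
spacing; two detected points use their single distance, fewer leave the
image flagged `unscaled`.

Numerical choices that matter:

* **Minimum peak separation** is `min_sep_fraction` (default 0.4) of the
  template's pairwise distance, not the full distance: laser spacing
  shrinks with altitude, and the mask already constrains the location.
* **Signal floor.** Realistic brownish sediment keeps the laser signal
  baseline positive (for neutral gray, $I^{(LS)} = 0.6\,I^{(R)}$), so a
  floor at a multiple of the median would reject everything. Peaks must
  instead exceed `median + 5 * MAD` of the signal — a robust outlier rule
  with the same intent (suppressing noise maxima).
* Detection runs on the **original** images; contrast enhancement
  deliberately destroys the red-channel dominance the detector relies on.

On synthetic surveys spanning 1–4 m altitude the median relative scale
error is well below 1% (the acceptance bound is 2%).

# Color normalization

The chain is fixed: raw $\to$ illumination-corrected $I^{(IL)}$ $\to$
contrast-enhanced $I^{(HE)}$ $\to$ histogram-matched $I^{(IN)}$ $\to$
footprint-standardized.

**Illumination drop-off** is removed by local z-scoring: per channel, a
smooth illumination field (mean and standard deviation under a triple-box
filter whose support is about one quarter of the image diagonal) is
estimated, and the channel is re-expressed as
$(x - \mu_{loc})/\sigma_{loc} \cdot \sigma_t + \mu_t$ with the targets
taken from the survey's reference image. This follows the gray-world
reading: the smooth field carries the lighting, the residual carries the
scene. A global z-score cannot remove a *spatial* gradient, which is why
the local form is used. The step is idempotent up to roughly 3 RMS
intensity levels — re-applying it re-estimates the local standard
deviation across nodule texture boundaries, a second-order effect we
document rather than hide.

**Contrast enhancement** is CLAHE on the luma channel (8 × 8 tiles),
with chroma preserved by applying the luma gain to all channels. The clip
limit is 0.03 of the tile histogram mass. The conventional 0.01 caps the
equalization slope at $0.01 \times 256 \approx 2.6$, which cannot spread a
40-level histogram over the 8-bit range; 0.03 (slope cap ≈ 7.7) restores
the intended behavior while still limiting noise amplification. Histogram
entropy never decreases on the package's fixtures, and this is asserted in
the tests.

**Histogram matching** selects the reference image as the one with the
maximum scale (acquired closest to the seafloor, ties to the earliest
image) and matches every channel to the reference ECDF by *rank mapping*:
pixel ranks, ties broken deterministically by pixel order, are sent
through the inverse reference ECDF. Unlike level-based LUT matching, whose
error is bounded only by the largest single-level mass, rank mapping
reproduces the reference ECDF to within $1/n$ at every percentile and is
exactly the identity on the reference itself.

**Footprint standardization.** With per-image scales $S_i$ and survey
median $S^M$ (even $N$: mean of the two central order statistics), each
image is resampled by the factor $S^M / S_i$ with cubic (Catmull–Rom)
interpolation, so every image lands at the median scale, then
center-cropped to a fixed size. The default crop of 2240 × 3360 px at
21.6 px/cm covers $2240 \cdot 3360 / (21.6^2 \cdot 10^4) \approx 1.61$
m² of seabed. The printed scaling factor in the source convention is
$F^i = S_i / S^M$; we resize by its inverse so that images *land at* the
common scale rather than being scaled away from it — resizing by $F^i$
itself would upsample exactly the highest-resolution images, contradicting
the stated common working resolution.

# Features and embedding

Each standardized image is summarized by six numbers: median convex-hull
area of the dark components, 75th-percentile component area, total
component area, density (total area over image area), component count, and
the summed local entropy (base-2 Shannon entropy of the intensity
histogram over a 5 px disc around every pixel). Components come from
thresholding the lightly smoothed (3 × 3 box) grayscale and removing
components below `min_area` (20 px at the quarter-scale working
resolution). Convex-hull areas are measured over pixel squares, so a
filled 10 × 10 square has hull area exactly 100.

Thresholding is the one place the survey context matters. Otsu's method is
only meaningful when a dark mode exists; on a bare-sediment image the
histogram is unimodal and Otsu returns an arbitrary split of the noise.
Because every image is matched to the same reference histogram, the
pipeline derives a *single survey threshold* from the reference — the
midpoint between its dark-mode mean and its Otsu threshold — and applies
it to all images. Images genuinely lacking nodules then produce
near-empty masks, which is exactly the class-A signature. Standalone
`binarize_nodules()` keeps per-image Otsu as the default for controlled
inputs.

The feature matrix is standardized column-wise (constant columns get unit
scale with a warning) and projected to 2-D with PCA; for centered data the
linear-kernel PCA scores coincide with classical PCA scores, which the
tests verify against a kernel-matrix eigendecomposition. Axis signs are
fixed by forcing each component's largest-magnitude loading positive.

# Semi-automated labeling

Seed images are proposed by greedy farthest-point selection in the 2-D
embedding (a deterministic stand-in for an analyst choosing uniformly
spread examples; uniform coverage counteracts class imbalance). Each
seed's label is propagated to its `k_nn = 100` nearest non-seed images in
the standardized 6-D feature space — not the 2-D embedding, which is for
visualization. Expansion is disjoint: all (image, seed) pairs are
processed in order of increasing distance, each image is claimed once, and
each seed stops at its quota, so a contested image goes to the closer seed
(exact ties to the seed earlier in image-id order). With 50 seeds and 100
neighbors on a sufficiently large survey this yields exactly 5000 expanded
labels (5050 including seeds). Splits are stratified by class with
largest-remainder apportionment at 0.80/0.07/0.13 — the source's stated
percentages (80/7/12.2) are internally inconsistent, so the fractions are
configuration.

# Training-set sampling strategies

Four ways to draw an $n$-image training set for the unsupervised
classifier:

* **random** — uniform without replacement;
* **spatial** — images ordered by cumulative along-track distance
  (transects are one-dimensional; a 2-D grid variant would add bins that
  are empty away from the track), split into $n$ equal-count bins, one
  draw per bin;
* **stratified** — k-means over-clustering of the 1-D total-entropy
  feature into `n_strata = 20` strata, uniform quota per stratum, small
  strata exhausted with the deficit redistributed;
* **probabilistic** — a 20-component 1-D Gaussian mixture fitted to the
  entropy values by EM; draw weights proportional to the inverted density
  $1/\max(\hat f(x), \varepsilon)$ with
  $\varepsilon = 10^{-6} \max \hat f$, oversampling rare entropy regions.

`evaluate_strategy()` times sampling-through-fit and scores the resulting
k-means clustering by mean silhouette, the selection criterion between
strategies. On an 80/10/5/5 synthetic survey the stratified strategy's
class distribution is measurably closer to uniform (Jensen–Shannon
distance) than random sampling's, the mechanism behind its imbalance
reduction.

# Classification and evaluation

k-means (10 restarts) is fitted for each $k$ in 2..20 and the $k$ with the
highest mean silhouette wins, ties to the smaller $k$; silhouette is
computed on the training sample, matching the sample-then-fit order and
keeping the quadratic distance matrix tractable. Prediction is
nearest-centroid; the reported confidence is the margin
$d_2/(d_1 + d_2)$ between the two nearest centroids.

The supervised classifier is a pluggable contract: `fit` on labeled
images, `predict_proba` returning a distribution over classes. The
shipped desk-scale backend is softmax regression on the 6-D features
trained by full-batch gradient descent with Armijo backtracking (loss
provably non-increasing) for 200 iterations, logging loss and accuracy
curves — the same shape as fine-tuning a frozen-base CNN with a fresh
classification head, which is what the contract records
(`frozen_base = TRUE`, head widths). An actual ImageNet-pretrained CNN
backend would slot in behind the same contract but needs accelerator
hardware and pretrained weights, deliberately outside the desk-scale
scope.

Metrics: confusion matrix, macro and support-weighted F1, Cohen's kappa
(chance-corrected, symmetric, *not* label-permutation invariant), and the
Fowlkes–Mallows index (pair-counting, therefore permutation invariant),
verified in the tests against exhaustive pair enumeration over all set
partitions of 4–5 items and sampled partitions of 6. Cluster-to-class
comparison uses majority-vote mapping on the intersection set.

# Synthetic scenes: what they emulate and what they do not

The generator states a small physical world: a pinhole camera
($s = f/\mathrm{altitude}$, $f$ chosen so a full 4480 × 6720 frame gives
43.2 px/cm at 1 m and 21.6 px/cm at 2 m); sediment with Gaussian texture
noise; nodules as anti-aliased dark ellipses with physical (cm) lognormal
radii at class-specific densities per m² (A: 3/m², B: 30/m², C: 120/m²,
D: 25/m² with the largest radii — ordered as the class definitions
require); light attenuation $e^{-0.15\,\mathrm{alt}}$ so higher images are
darker; a radial vignette saturating at 70% of the corner distance; three
red laser discs at the exact triangle geometry; and a linearly
interpolated tow track photographed every 10 s at altitudes uniform in
1–4 m with ±25% per-image brightness jitter. Physical radii (not pixel
radii) are used so that footprint standardization makes features
altitude-invariant — the premise the real workflow relies on.

Test frames default to 280 × 420 px (1/16 linear of the survey camera,
focal constant scaled accordingly) to keep runtimes inside CI budgets;
the rendering model is resolution-independent.

A green synthetic test establishes that the implementation recovers known
parameters under the stated model. It does not establish performance on
real imagery: the generator has no water-column scattering, no motion
blur, no biological cover, no spatial autocorrelation of classes along
the track, and its laser dot profile is an idealized disc; real laser
detection contends with reflections and substrate-dependent absorption.

# Degenerate inputs and tie-breaks

Collinear template annotations are rejected ("degenerate triangle"); zero
detected lasers is a flagged result, not an error. Zero-variance channels
pass through at the target mean with a warning. Constant feature columns
get unit scale. Reference selection, seed proposal, contested-image
assignment and cluster-to-class mapping all have documented deterministic
tie-breaks (earliest id / lower id / alphabetically first). All
randomness flows from explicit seeds; every stage is reproducible
byte-for-byte.

# Known limitations

* The supervised backend is linear in the six features; fuzzy class
  boundaries in real imagery need the CNN backend the contract leaves
  room for.
* Silhouette-based $k$ selection has the well-known bias toward coarse
  partitions: on a minority of synthetic survey draws its global maximum
  lands one below the generative class count, merging the two nearest
  classes (sparse and patchy nodules) even though k-means at the correct
  $k$ separates them almost perfectly (cluster-to-truth kappa ≥ 0.95).
  Variance-stabilizing feature transforms (sqrt, log, rank) only move the
  merge to a different class pair, so the plain column standardization is
  kept and the behavior is documented instead.
* Georeferencing is nearest-fix in time (30 s default gap), not
  interpolation; adequate at one fix per image, coarse for sparse
  navigation.
* The local-entropy kernel is quadratic in the disc radius; very large
  radii on full-resolution frames are slow.
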