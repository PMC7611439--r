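---
title: "Methods: symmetry scoring, perceptual-distance models and symmetry-augmented classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symmetry scoring, perceptual-distance models and symmetry-augmented classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symperc)
```

This vignette is the package's account of its own methods: the models it
implements, the conventions and defaults it commits to, what its
synthetic data generator does and does not emulate, and where the design
was genuinely open.  It states no empirical result that the test suite
or the acceptance script does not itself compute.

## 1. Strength of symmetry

For an image `A` (a non-negative intensity raster) and an in-plane axis
through the image center, the strength of reflection symmetry is

$$S = 1 - \frac{\sum |A - R|}{\sum (A + R)},$$

where `R` is the reflection of `A` about the axis and sums run over all
pixels.  `S` is 1 exactly when the image equals its reflection pixel for
pixel, 0 exactly when image and reflection have disjoint support, and
lies in `[0, 1]` for any non-negative image because the numerator never
exceeds the denominator pointwise.  The score is invariant to global
intensity scaling.

Conventions the implementation commits to:

* **Axis through the center.** All scoring assumes centered objects;
  axis localization is out of scope.  For an even width `W` the vertical
  mirror maps column `c` to `W + 1 − c`, i.e. the axis runs between the
  two middle columns.  The same convention is used for rows and for the
  center of rotation, so cardinal-axis reflection, right-angle rotation
  and scoring are mutually consistent and *exact* (pure pixel
  permutations).
* **Angle convention.** Axis angle 0° is the vertical axis, increasing
  counter-clockwise; 90° is the horizontal axis.  `symmetry_profile()`
  samples `k·180/n` degrees, `k = 0..n−1`; the default `n = 8` gives the
  feature vector used for classifier augmentation.
* **Oblique axes.** For angles other than 0/90 the image is rotated so
  the axis becomes vertical, flipped, and rotated back, with bilinear
  interpolation and zero fill.  Interpolation makes oblique scores
  approximate: the test suite holds a centered disk to all-axis scores
  within 0.02 and rotated-object consistency within 0.05, and those are
  the tolerances we advertise.
* **Background.** Sums include every pixel present.  On the package's
  silhouette stimuli (background exactly 0) this is unambiguous; on
  gray-level images background intensities dilute the score, which is a
  property of the measure, not a bug.  Area for the pair-level
  `area_ratio()` counts pixels above half the per-image maximum, again
  unambiguous on silhouettes.
* **Pair-level strength.** Vertical-axis scores are averaged over the
  two images of a pair, horizontal likewise, and the pair strength is
  the larger of the two means.  Skew (out-of-plane) symmetry is not
  modeled.

## 2. The stimulus generator

`make_part_library()` draws `n` distinct part silhouettes as thresholded
low-pass-filtered white-noise fields (smooth random blobs) in a part box
of 0.3 × canvas, with a small tab forcing contact with a centered
horizontal stem; the canvas default of 140 px matches the standard
square frame for this kind of stimulus work.  Part geometry is
otherwise arbitrary by design: what matters downstream is the
*compositional* structure, not the artwork.

`compose_two_part_objects()` forms all `n²` ordered (left, right)
combinations.  The right-end instance of a part is the horizontal mirror
of its canonical form, and the stem's column support is invariant under
the mirror, so same-part objects are *pixel-exact* mirror symmetric —
the score-1 boundary case is true by construction, not approximately.
A consequence worth noting: the full object set is closed under
left-right mirroring (the mirror of object AB *is* object BA), which
Section 6 exploits.  Parts abut the stem rather than overlapping it;
nothing downstream depends on that choice.

With 7 parts this yields the canonical 49-object set: C(49,2) = 1,176
pairs, C(7,2) = 21 symmetric–symmetric pairs, and 420 "AB–CD" pairs
(both objects asymmetric, no shared part; `n(n−1)(n−2)(n−3)/2`).
`rotate_set()` produces the vertically oriented variants by lossless
quarter turns, mapping vertical-axis symmetry onto the horizontal axis.

### The synthetic dissimilarity world

`simulate_dissimilarities()` writes, for each pair,

$$d_{ij} = \sum_k w_k |x_{ik} - x_{jk}| + \beta_{sym} S_{ij}
  + \beta_{area} \log AR_{ij} + \varepsilon, \qquad
  \varepsilon \sim N(0, \sigma^2),$$

clipped below at a small positive floor, in units of 1/seconds.  The
defaults are the package's stated world: `beta_sym = 0.5` makes mean
symmetric-pair dissimilarity exceed disjoint-asymmetric pairs by roughly
0.2 s⁻¹ (the size of the symmetry advantage reported for measured search
data, where symmetric pairs sit near 1.36 s⁻¹ against 1.16 s⁻¹ for
asymmetric ones); `beta_area = 0.1` per log-unit of area ratio;
`noise_sd = 0.1` s⁻¹ is of the order of trial-to-trial variability when
a handful of reaction times around one second are averaged; the floor of
0.05 s⁻¹ keeps generated distances positive (a 20 s search is already
far beyond task timeouts).  These values were chosen once, for the
reasons above.

What the generator emulates: the compositional pair structure (shared
parts), a symmetry bonus, an area-ratio effect, additive noise, and
linearity in per-component absolute feature differences.  What it does
not: subject-level variability structure beyond iid noise, search
asymmetries, set-size effects, natural-image feature statistics, or any
nonlinearity in how features combine.  A green test on this world
therefore establishes that the *analysis machinery* recovers what was
put in — not that real perceptual data obey the model.

## 3. Perceptual-distance fitting

`fit_weighted_pc_distances()` solves, by ordinary least squares with no
intercept, the model that predicts a pair's dissimilarity as a weighted
sum of absolute per-component differences.  Open choices and how we
resolved them:

* **Constraints.** Whether such weights should be constrained
  non-negative is not fixed by the model; we default to unconstrained
  OLS (exactly solvable, unbiased) and expose `nonneg = TRUE`
  (projected-gradient NNLS) for users who want sign-constrained
  contributions.
* **Cross-validation.** 10 repeated random 80/20 pair splits, seeded;
  the reported `r` is the Pearson correlation between predictions and
  observations on held-out pairs (Pearson is used for every correlation
  in the package).  Folds never overlap their training sets, and the
  test suite asserts this.
* **Rank deficiency.** Singular designs fall back to the minimum-norm
  solution with a warning rather than failing.

`fit_comb2()` applies the same solver when the columns are per-model
distances rather than component differences (`y = Xb`), reporting `b`
for inspection.  `comb1_concat()` implements the feature-level
alternative: z-score each feature across images, concatenate, reduce by
centered PCA.  PCA signs are fixed (largest-magnitude loading positive)
so reductions are deterministic; predictions of the distance model are
invariant to component sign in any case, because only absolute
differences enter.

**Reliability ceiling.** `split_half_reliability()` splits subjects into
random halves, correlates per-pair means across halves, and averages
over 20 seeded splits (a single split is an unnecessarily noisy estimate
when resplitting is free).  The Spearman–Brown correction
`r_c = 2r/(1+r)` converts the half-data correlation into the ceiling for
a model trained on all the data, and
`variance_explained(r_m, rc) = 100 (r_m/r_c)²`.  With the commonly
printed rounded values `r_m = 0.74` and split-half `r = 0.81` this
formula gives 68.4% — a number the test suite recomputes; unrounded
inputs land a few tenths lower.

`leave_one_group_out()` implements the generalization check: train on
all experiments but one, test on the held-out experiment, report its
variance explained against its own (or a pooled) reliability ceiling.

## 4. Residual diagnostics

Residuals are observed − predicted, in 1/seconds.  Flags mark pairs more
than one standard deviation from the *mean* residual (the distance model
has no intercept, so training residuals need not average zero; centering
on the mean makes "±1 sd" meaningful either way; when sd = 0 nothing is
flagged).  `correlate_residuals()` reports Pearson r with a two-sided p
and, optionally, a pair-resampling bootstrap sd and percentile CI; no
multiple-testing correction is applied within this module.
`bin_residuals_by_shared_parts()` averages residuals for pairs sharing
two, one or no parts, reporting empty bins as missing.

`mds_embed()` is metric stress MDS, implemented as SMACOF (Guttman
majorization) with one classical-scaling start plus nine seeded random
restarts, keeping the lowest-stress solution.  (No suitable
stress-majorization implementation was available among the package's
allowed dependencies, so it is implemented here; classical scaling is
used only for initialization.)  The quality figure `embedding_r` is the
Pearson correlation between embedded and input distances.  Missing
entries are tolerated up to 20% and imputed by column means with a
warning; beyond that the embedding errors out.

## 5. Late fusion of symmetry and base classifiers

"Linear classifier" is concretized as a two-class linear discriminant:
shared covariance, equal priors, posterior equal to the logistic of the
discriminant score.  A singular pooled covariance is ridge-regularized
with `λ = 1e−6·trace/d`.  Logistic regression would be an acceptable
alternative; LDA is the classical choice for this pipeline and is exact
under the Gaussian simulations the tests use.

The three-stage pipeline (`train_fusion()`):

1. base classifier on extractor features, 10-fold cross-validated;
2. symmetry classifier on the 8-axis symmetry profile, likewise;
3. fusion classifier on the *two posterior scores only*.

Two guards matter.  First, the fusion stage consumes posteriors
produced **out of fold** — each example's posterior comes from the fold
in which it was held out — otherwise the stacked classifier trains on
optimistically overfit scores.  Second, an outer held-out split (default
20%) is carved out before any training and is the only data on which
accuracies are reported.  Per-category benchmarking
(`fusion_category_benchmark()`) runs one-vs-rest with an equal number of
seeded negative examples per category and compares fused against base
accuracies across categories with a two-sided rank-sum test.
`feature_concat_baseline()` provides the early-fusion comparison: one
classifier on z-scored concatenated features under the same outer split.

One calibration note: a "chance = 50 ± 2%" check on shuffled labels is
only meaningful when the held-out set is large enough that binomial
noise is small against the band; the tests use 2,000 held-out examples
(sd ≈ 1.1 percentage points) rather than 400.

## 6. Probing networks

`make_toy_network()` builds the desk-scale stand-in for a deep
network's final stages: a rectified projection as feature extractor and
a softmax head trained by full-batch gradient descent.  By default the
projection is a fixed random one and only the head trains.  That
default has a consequence worth stating plainly: the penultimate
activations are then *independent of training*, so any analysis of how
training shapes the representation requires `train_extractor = TRUE`,
which backpropagates into the hidden layer.

* **Unit importance.** `unit_importance()` ablates one unit at a time
  by zeroing its outgoing weight row (extractor untouched, original
  network restored) and averages the absolute change in true-class
  softmax probability over 20 seeded, correctly classified probe images
  drawn from distinct classes where possible.  Softmax probabilities
  (not pre-softmax scores) are used; the definition is stated in terms
  of output class probabilities and softmax is what a classification
  head outputs.  The test suite holds every per-unit value to a
  brute-force oracle that rebuilds the head without the unit, to 1e−10.
  Top/bottom unit sets default to `k = n_units/10`, the proportional
  analogue of taking 100 units from a 4096-unit layer.
* **SMI.** Distances are Euclidean over penultimate activations
  (restricted to a unit subset when asked), without per-unit z-scoring;
  z-scoring would reweight units and change the index, and nothing in
  the definition calls for it.  `bootstrap_smi()` resamples the
  symmetric and asymmetric pair sets with replacement at their own
  counts (21 and 420 for the 49-object set), 10,000 replicates by
  default.
* **Spatial frequency.** `sf_modulation()` averages each unit's
  activation across 8 orientations at each of 6 frequencies and
  contrasts the high group (0.25, 0.33, 0.5 cycles/px) against the low
  group (0.06, 0.09, 0.17).  Gabor phase defaults to 0° and envelope
  sigma to size/5 — cosmetic choices; the index contrasts within-unit
  averages and is insensitive to them.

### Emulating the mirror-augmentation contrast

The question "does flip augmentation during training create the
symmetry advantage?" needs two nets whose *representations* differ by
training regime.  Because the two-part object set is closed under
mirroring, adding mirror images of the full set is a no-op — the
augmented and plain training sets are identical, and a naive emulation
silently compares a network with itself.  The package's tests therefore
train the no-augmentation net on only the canonical orderings (left
part index ≤ right part index) and the augmented net on the full set
(canonical images plus their mirrors, which is the same thing), with
mirror-invariant labels (the unordered part pair).  Across five seeds
the augmented nets show a clearly higher symmetry modulation index on
the probe set; intuitively, mirror-invariant training folds each object
and its mirror onto similar representations, which shrinks distances
among asymmetric objects (every one has a distinct mirror partner)
while symmetric objects, being their own mirrors, are unaffected.

## 7. Numerical and infrastructure choices

* PNG I/O is 8-bit grayscale; intensities are quantized before writing
  so round trips are pixel-exact and the worst-case quantization error
  is 1/255.  Metadata travels in a sidecar `manifest.csv`.
* CSV outputs are written at 9 significant digits, which is what makes
  "same seed ⇒ byte-identical outputs" an assertable CLI property.
* Every stochastic operation takes an explicit seed; CLI exit codes are
  2 for configuration errors, 3 for missing inputs, 1 otherwise.
* Degenerate inputs error early with specific messages: all-zero images
  for symmetry scoring (zero denominator), empty objects for area,
  constant labels for classification, constant covariates for
  correlation.

## 8. Known limitations

* Oblique-axis symmetry scores inherit bilinear-interpolation error;
  scores within ~0.02 of each other at oblique axes should not be
  ranked.
* The generator's parts are random blobs; analyses that depend on
  natural part geometry (curvature statistics, recognizability) have no
  synthetic counterpart here.
* The toy network is a one-hidden-layer stand-in.  It supports the
  probing *contracts* (ablation, SMI, spatial-frequency tuning) and the
  training-regime contrast, but its absolute index values say nothing
  about any particular deep network; adapters for real networks must
  supply their own extractor and head.
* Reliability correction assumes split halves are exchangeable;
  strongly heterogeneous subject pools violate this silently.
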