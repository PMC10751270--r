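---
title: "fexkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fexkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fexkit is a desk-scale facial expression analysis toolkit: it detects facial
action units (AUs) and emotion categories from face images given 68-point
landmark annotations, visualizes arbitrary AU combinations on a stylized
face, and analyzes the resulting frames-by-features (Fex) tables with the
session-aware statistics common in affective science. This vignette explains
the models behind each stage, the parameters that matter, and the design
choices that were genuinely open — including what the synthetic data
generator does and does not emulate, and therefore what the package's tests
do and do not show about real face data.

## The detection pipeline

AU and emotion detection follows the classic shallow pipeline for posed-face
analysis: geometric normalization, oriented-gradient features inside the
face region, linear dimensionality reduction, and per-target shallow
classifiers.

1. **Alignment** (`align_crop`). A similarity transform (uniform scale plus
   translation; no rotation) maps the landmark bounding box, expanded by
   10%, onto a square patch of `patch_size` pixels (default 112). Rotation
   is deliberately not removed: in-plane rotation robustness is something we
   want to *measure* (see below), not silently correct. Resampling is
   bilinear; the same transform is applied to the landmarks so every
   downstream step sees a consistent frame.
2. **Hull masking** (`convex_hull_mask`). Pixels outside the convex hull of
   the 68 landmarks are zeroed *before* gradients are computed. This creates
   a gradient edge along the hull boundary; that edge is the face outline
   and carries shape information, so it is accepted rather than suppressed.
   Pixel centers on the hull boundary count as inside.
3. **HOG** (`hog_features`). Unsigned gradient orientations (folded to
   [0, &pi;)) are hard-assigned to 8 bins, magnitude-weighted into 8x8-pixel
   cell histograms, and normalized in overlapping 2x2-cell blocks with
   L2-Hys (L2, clip 0.2, renormalize). These are the conventional HOG
   settings; all four are exposed through `detector_config()`. The feature
   length is `(P/cell - block + 1)^2 * block^2 * orientations` — 5408 at the
   defaults.
4. **PCA** (`fit_pca`). Principal components of the training HOG matrix,
   keeping the smallest number of leading components that explain 95% of the
   variance (configurable). On the default synthetic training set this is a
   few hundred components.
5. **Classifiers** (`train_au_detector`, `train_emotion_detector`). One
   independent binary classifier per AU — either gradient-boosted trees
   (default; depth 4, learning rate 0.3, 150 rounds, single thread for
   reproducibility) which emit probabilities directly, or a linear SVM whose
   margin is mapped through a Platt-style logistic link fitted on the
   training margins. The link's slope is constrained non-negative by
   orienting the margin, so probability is monotone in the decision value.
   Class imbalance is handled with inverse-frequency weights. The emotion
   classifier is one-vs-rest linear SVMs with calibrated per-class
   probabilities normalized to sum to one. Binary AU calls use a fixed 0.5
   threshold, set once alongside the generator calibration (below) and not
   revisited.

Everything is assembled by `fit_detector()` into a single `detector_bundle`
(PCA basis, classifier parameters as plain numeric arrays, preprocessing
configuration, training metadata) that serializes bit-exactly and refuses
inputs preprocessed under a different configuration.

## The AU-to-landmark face model

Visualization and synthesis share one generative model
(`au_face_model`): a neutral 68-point template in a normalized frame
(centroid at the origin, interocular distance 1, y pointing down) plus a
linear deformation map `W` (136 x K), so that

    landmarks(au) = template + reshape(W %*% au).

Linearity buys exact additivity of deformations, a zero-activation identity,
and affine morph trajectories — the three contracts `plot_face()` and
`animate_face()` are tested against. `fit_face_model()` estimates `W` by
per-coordinate ordinary least squares (the simplest model consistent with a
2D landmark deformation view; partial least squares could be swapped in
behind the same interface). If rows with all-zero activations are present
their mean shape is the template and the regression has no intercept;
otherwise the intercept becomes the template. A rank-deficient activation
matrix is refused with the dependent columns named.

The packaged default model (`default_face_model()`) uses hand-designed
deformation directions for the 12 detectable AUs, in interocular units per
unit activation: inner/outer brow raises for AU1/AU2, brow lowering for AU4,
eye-aperture changes for AU5/AU6, nose-base lift with nostril flare for AU9,
mouth-corner pulls for AU12/AU15/AU20, chin raise for AU17, lip parting for
AU25 and jaw drop for AU26. Magnitudes (0.03–0.20) were chosen once so that
every AU's movement is visibly resolvable at the default render scale
(~32 px interocular distance), the way these movements are visible to a
human coder; they are a package convention, not an estimate from any corpus.
Muscle heatmaps (`default_heatmap_spec()`) place radial overlays at
hand-curated anchor landmarks per AU (brows for 1/2/4, lids for 5, cheeks
for 6, nose root for 9, mouth corners for 12/15/20, chin for 17/26, lips
for 25) with a 0.12 interocular-unit falloff, truncated at three falloffs so
the overlay has finite support.

## The synthetic generator and what it does (not) emulate

`make_dataset()` renders labeled stylized faces: an AU activation vector is
drawn, pushed through the face model, placed on a mid-gray canvas
(`min(canvas)/3.5` pixels per interocular unit, default canvas 112x112),
jittered with Gaussian landmark noise (sd 0.5 px), and rasterized with
anti-aliased dark polylines, filled eye polygons, filled lips and a bright
tooth region in the mouth opening — deliberately cartoon-like, but with
enough gradient structure for HOG. The activation law is a mixture: 60% of
faces are emotion prototypes (the AU pattern of one of seven categories
under an EMFACS-style map restricted to the 12 detectable AUs:
happiness {6,12}, sadness {1,4,15}, surprise {1,2,5,26},
fear {1,2,4,5,20,26}, anger {4,5,17}, disgust {9,15,25}, neutral = none),
and 40% are free expressions with independent per-AU Bernoulli(0.25)
occurrences; active AUs draw intensities uniformly from [0.5, 1]. Emotion
labels come from exact pattern matching, with everything else labeled
neutral.

`make_fex_timeseries()` emulates per-frame detector output for a two-condition
("good" vs "bad" news) design: each AU channel fluctuates around the
maximal-uncertainty baseline 0.5 with AR(1) noise (coefficient 0.7,
innovation sd 0.08 per video plus a condition-shared AR(1) component of
sd 0.05), and the good-news condition raises AU06/AU12/AU25 by
0.20/0.25/0.20. The shared component is what gives intervideo correlations
their condition structure; the per-video autocorrelation is what makes
video-grouped cross-validation meaningfully harder than frame-level folds.
Effect sizes were fixed to the magnitude a strong naturalistic manipulation
produces (condition means around 0.7 against the 0.5 baseline).

What this world does **not** emulate: photographic texture, identity and
demographic variation, out-of-plane pose, illumination gradients,
correlated AU co-activation beyond the prototype patterns, annotation bias,
or detector miscalibration. Passing the end-to-end tests therefore shows the
pipeline is *correct and internally consistent* — features carry AU
information, classifiers recover it, lesions degrade the right AUs — not
that any particular accuracy transfers to real faces.

## Statistics on Fex tables

`extract_summary()` aggregates per session; `isc()` computes pairwise
correlations of one channel across sessions, truncating unequal series to
the shortest (with a warning) and reporting zero-variance series as missing
rather than zero. `fex_regress()` is mass-univariate ordinary least squares:
the same design fit independently to every outcome column, with shared
degrees of freedom, two-tailed t-based p values, and no multiplicity
correction by default (a Benjamini–Hochberg option exists) — uncorrected
per-AU tests are the convention this mirrors. When sessions are numeric
contrast codes they are used directly as the regressor, so a +/-1 contrast
with intercept reproduces the pooled two-sample t test exactly; this
equivalence is the module's headline test oracle. Note that frame-level
regression treats frames as independent: on autocorrelated time series with
condition-shared noise (exactly what the synthetic generator produces) the
effective degrees of freedom are far below `n - p`, so small spurious
effects can reach nominal significance. The calibration guarantee (5% false
positives at p < 0.05) holds for independent rows; for time-series designs
the per-video summaries from `extract_summary()` are the safer regression
substrate.

`predict()` on a Fex table decodes the session label with k-fold
cross-validation **grouped by video**: frames are temporally autocorrelated,
so frame-level folds would leak near-duplicate frames across the boundary
and inflate accuracy. Whether the original analysis this mirrors stratified
folds by frame or by video is not documented; grouping by video is the
conservative choice and is asserted structurally in the tests. Videos are
dealt round-robin to folds within each class after a seeded shuffle, the
final decoder is refit on all data, and its coefficient vector is exposed so
the decoded contrast can be rendered with `plot_face()`.

## Metrics and robustness

`average_precision()` implements score-ranked greedy matching (highest-IoU
unmatched ground truth in the same image, IoU >= 0.5) with all-points
interpolation — the exact area under the interpolated precision–recall
staircase, with score ties broken deterministically by input order. Landmark
error is RMSE over the 68 points normalized by the ground truth's
interocular distance, defined as the distance between the two eye-center
means (stable under per-point jitter, unlike corner-based definitions). Pose
error is per-axis mean absolute error in degrees; AU/emotion calls are
scored with F1.

Perturbations: luminance scaling with factors drawn uniformly from
[0.1, 0.8] (low) or [1.2, 1.9] (high) and clipped; black-mask occlusion of
the eyes, nose or mouth via landmark-derived region boxes (pad 2 px), where
the eyes region deliberately includes the brows because AUs 1/2/4 live
there and an eye mask that spared brows could not lesion them; and in-plane
rotation about the landmark centroid applied consistently to pixels and
landmarks. In-plane rotation is a desk-scale stand-in for out-of-plane head
rotation and is labeled as such wherever results are reported.

## Numerical conventions

Pixel coordinates are 0-based, x rightward, y downward, with the pixel at
matrix position `[r, c]` centered at `(c-1, r-1)`; boxes are `(x, y, w, h)`;
hull and polygon boundaries are inclusive. Intensities live in [0, 1];
8-bit images are converted on read by the CLI. Landmark vectors stack all x
then all y. All stochastic steps (training, sampling, fold assignment,
brightness draws) take explicit seeds and restore the caller's RNG state;
datasets regenerate bit-identically from their recipe, and rendering is
bit-deterministic.

## Problem sizes

The test suite and the acceptance script train the default bundle on 2000
synthetic faces and evaluate on an independent 400-face set (separate
seeds), run robustness evaluations over three occlusion regions and four
rotation angles on the test set, fit the face model recovery at n = 500
with landmark noise sd 0.01, and analyze time series of 10 videos per
condition x 300 frames. These sizes give stable estimates (binomial SE on a
per-AU F1 at n = 400 is about 0.015) at desk scale.

## Known limitations

- Detectors require landmarks as input; no face/landmark/pose detection
  from raw pixels is included — ground truth (or any external detector)
  provides them through a plain CSV interface.
- The stylized renderer has no texture, so HOG statistics differ from
  photographs; absolute accuracies on synthetic data are not transferable.
- The linear face model cannot represent saturating or interacting
  deformations (e.g. AU12+AU25 combinations simply add).
- AU intensity is generated but detection is occurrence/probability only;
  no intensity regression is provided.
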