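---
title: "Methods: temporal-spatial regression features for walking skew"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal-spatial regression features for walking skew}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skewgait)
```

## The model

A walking video, reduced to per-frame BODY_25 keypoints, is summarised per
walk by three numbers. Frames are sampled on the grid `t_k = k · Δt`
(default Δt = 0.3 s). Per sampled frame the *iso-block* is the axis-aligned
bounding box of the keypoints whose confidence exceeds a threshold; its four
corners are tracked in Cartesian pixel coordinates (image rows flipped so y
grows upward). Per corner `c ∈ {lt, rt, lb, rb}` an ordinary least-squares
line `y_c,i = α_c + β_c x_c,i + ε_c,i` is fitted across the `N` sampled
frames, and the walk's features are

* `TAR = sign(β_lt) atan(β_lt) / [sign(β_rt) atan(β_rt)]`,
* `BAR` analogously for the bottom corners, and
* velocity = known path length / traversal time.

`sign(β)` is −1 for negative slopes and +1 otherwise (so `sign(0) = +1`);
each product `sign(β) atan(β)` equals the magnitude of the angle between the
corner trajectory and the x-axis, so TAR and BAR are nonnegative and
unit-free (the radians/degrees choice cancels in the ratio).

Why this works: under a pinhole camera, a walker approaching on a straight
line produces corner trajectories that are *linear in the projection scale*
`s = f / depth`. For a centred, symmetric body the left and right corner
slopes are mirror images, so both ratios are exactly 1. A constant heading
offset adds a lateral pixel drift that is itself linear in `s`, steepening
one top corner's trajectory and flattening the other — TAR and BAR move off
1 in a direction determined solely by the side the walker veers toward.

### Assumptions

* One walker per video, full body visible, static camera, known path length.
* Straight-line heading during each walk (the offset model below); curved or
  lurching trajectories are outside the model.
* Each walk is analysed separately; a round trip yields two independent
  feature vectors.
* Missing keypoints are encoded as confidence 0 and excluded everywhere; a
  frame needs at least two confident keypoints spanning a nonzero box.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `interval_s` | 0.3 | s | the sampling grid at which a 3 s video yields 10 frames; coarse enough for distinct postures, fine enough for overlapping silhouettes (see `sampling_sufficiency`) |
| `conf_threshold` | 0.1 | – | drops pose-estimator guesses while keeping weak but real detections |
| `sigma_px` | 3 | source px | DJNP kernel width: a joint's visual footprint at 1080p |
| `downscale` | 4 | – | 1920×1080 → 480×270 grid; desk-scale memory |
| `folds` | 10 | – | standard stratified CV depth for ~200 samples |
| `C` | 1 | – | SVM soft-margin cost; no tuning claims are made |
| `gamma` | `1/(d·var)` | – | the usual "scale" heuristic on standardised features |

## The synthetic generator: what it emulates, what it does not

`generate_walk()` projects a fixed 25-joint stick body (1.66 m tall, 0.58 m
arm span) through a pinhole camera (focal constant 1000 px, camera 1 m above
the floor, 2 m from the near end of a 5 m path), at 30 fps and 0.68 m/s by
default — the recording geometry the pipeline is calibrated to. Limb swing
is a sinusoid at the stride frequency applied *vertically* (swing-foot lift
and arm pump, anti-phase left/right). Keeping the swing out of the depth and
lateral axes is deliberate: each projected frame then remains exactly
left-right symmetric, so a noise-free straight walk has a constant
bounding-box centre and TAR = BAR = 1 to machine precision, which pins the
feature semantics in tests. Measurement error is i.i.d. Gaussian pixel
jitter plus independent confidence-0 dropout.

**Skew is defined in the walker's body frame**: positive `skew_deg` drifts
toward the walker's own left, with lateral offset `tan(skew) × distance
walked`. A viewer-frame definition was rejected because perspective reverses
its effect between the two legs of a round trip — the same viewer-left drift
yields ratios above 1 walking away and below 1 walking toward — whereas a
body-frame veer lands on the same side of 1 for both legs, which is the
behaviour the feature is meant to capture and the convention the calibration
tests pin.

One geometric caveat, verified analytically and in tests: on *toward* legs
the lateral drift per unit `s` is proportional to the far (start) depth, so
at large skews the near-side corner trajectory passes through vertical and
`|TAR − 1|` is no longer monotone in skew. Monotonicity is therefore
property-tested on away legs ({0, 2, 5, 10}°); the direction of the effect
(left ⇒ > 1, right ⇒ < 1) holds for all skews on both legs and is tested for
both.

What a green test does **not** establish: the generator has no camera
distortion, no 3D limb kinematics, no curved or hesitant trajectories, no
occlusion structure in its dropout, and its group separations are far
cleaner than real cohorts. Green means the pipeline implements the stated
mathematics and recovers planted structure — not that it would reach the
same operating characteristics on clinical video.

`simulate_features()` skips the image pipeline and draws `(TAR, BAR,
velocity)` from per-group Gaussians. Its default means and dispersions are
the published-scale calibration template for a 85/36/89 cohort; the
dispersion multiplier `sd_scale = 0.18` was set so that the *Bayes*
accuracy of the resulting mixture (computed by Monte Carlo from the known
densities and priors) equals 0.990, the headline accuracy this low-noise
world is meant to emulate. At the full printed dispersions the three
marginal Gaussians overlap too much for any classifier to approach that
accuracy — the published classifier evidently exploited joint structure the
marginal table cannot encode — so the full-dispersion world is *not* used as
a classification benchmark.

## Numerical and design choices

* **Axis convention.** Corner coordinates are Cartesian (y flipped at
  feature extraction, never at I/O). The convention is pinned by the
  calibration tests (left skew ⇒ TAR, BAR > 1), so it cannot silently flip.
* **Sampling rule.** Grid anchored at `t = 0`; count `⌈D/Δt⌉` with
  `D = last timestamp + 1/fps`; "nearest frame" is `round(t_k · fps)`.
  Intervals finer than one frame period are errors.
* **DJNP kernels** are unit-mass over their own truncated (±4σ) window, so
  interior kernels contribute exactly 1 and grid mass counts keypoints;
  kernels are clipped at edges without renormalisation (documented loss).
  Merging is additive, not max-projection: additivity is what makes the
  conservation property testable.
* **Degenerate inputs.** Zero x-variance in a corner trajectory errors,
  naming the corner; a zero denominator angle (`β_rt` or `β_rb` = 0) marks
  the walk's features invalid rather than erroring, and invalid walks are
  excluded from classification with a logged count.
* **ROC cutting point**: thresholds are midpoints between adjacent distinct
  pooled values; the CP maximises Youden's `J = tpr − fpr`, ties broken
  toward the threshold nearest the midpoint of the two group means. AUC uses
  the rank (Mann–Whitney) identity with ties counted ½; its p-value uses the
  tie-corrected normal approximation. Orientation is auto-chosen so
  AUC ≥ 0.5, with the direction recorded.
* **SVM**: the binary dual is solved by SMO with maximal-violating-pair
  selection (stop when `m(α) − M(α) < 10⁻³`); multiclass is one-vs-one with
  vote-count ties broken by summed decision values; features are
  standardised with training-fold statistics only; fold predictions are
  pooled into a single confusion matrix because the report carries one
  recall/precision per class.
* **Velocity** is path length over the time span of frames with a valid
  iso-block — the only formula consistent with a fixed-length path and no
  calibrated image-to-world scale.
* **Kruskal–Wallis** uses the tie-corrected H with a χ² reference on
  G − 1 df; all-identical data returns H = 0.

## Known limitations

* The iso-block reduces posture to a bounding box: asymmetric arm carriage
  or clothing can move a corner without any heading change.
* The per-frame box construction from keypoints is an inference from the
  corner-tracking idea, not a prescribed algorithm; alternatives (convex
  hull, trunk-only box) would change the slopes' magnitudes though not the
  symmetry argument.
* TAR/BAR are undefined when a denominator slope is exactly 0 (flagged
  invalid), and unstable when the denominator angle is near 0.
* The SVM hyperparameters are sensible defaults, not a tuned configuration;
  no probability calibration is provided.
* ROC analyses are pairwise (straight vs each skew group); no multi-class
  ROC surface is attempted.
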