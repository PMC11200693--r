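# skewgait

Quantifying postural control from walking videos, without markers or
wearables. `skewgait` consumes per-frame 2D body keypoints in the OpenPose
BODY_25 layout (25 joints × `(x, y, confidence)` per frame) recorded while a
person walks a known path toward or away from a static camera, and reduces
each walk to three interpretable features that separate straight walking from
laterally skewed walking.

The package is aimed at movement scientists and rehabilitation researchers
who have pose-estimator output (they never need to run pose estimation here)
and want a per-video postural summary plus a classifier over walking-pattern
groups.

## The method

1. **Frame sampling.** Frames are taken every `Δt` seconds (default 0.3 s),
   anchored at the first frame: a 3 s video at 30 fps yields exactly 10
   frames.
2. **Dynamic joint-node plot (DJNP).** The sampled keypoints are merged
   additively into one heatmap (unit-mass Gaussian per keypoint), a
   whole-walk picture of body trajectory; a coverage score diagnoses whether
   the sampling interval leaves consecutive silhouettes overlapping.
3. **Iso-block corners.** Per sampled frame `i`, the axis-aligned bounding
   box of the confident keypoints; its four corners
   (`lt`, `rt`, `lb`, `rb`) are tracked across frames in Cartesian
   (y-up) pixel coordinates.
4. **Temporal-spatial regression (TSR).** Per corner `c`, ordinary least
   squares across frames:

   `y_c,i = α_c + β_c · x_c,i + ε_c,i ,  i = 1 … N`

   `atan(β_c)` is the angle between the corner's trajectory and the x-axis.
5. **Angle ratios.** With `sign(β) = −1` if `β < 0`, else `+1`:

   `TAR = sign(β_lt)·atan(β_lt) / [sign(β_rt)·atan(β_rt)]`
   `BAR = sign(β_lb)·atan(β_lb) / [sign(β_rb)·atan(β_rb)]`

   Straight walking gives TAR ≈ BAR ≈ 1; a walker veering to their own left
   pushes both above 1, to their right below 1. Velocity is the known path
   length over traversal time.
6. **Statistics & classification.** Kruskal–Wallis tests across groups; an
   RBF-kernel SVM (built in: SMO solver, one-vs-one, stratified 10-fold CV,
   pooled confusion matrix, Cohen's kappa) on `(TAR, BAR, velocity)`; ROC
   analysis (Mann–Whitney AUC, Youden-J cutting point) for pairwise group
   thresholds.

Because the kind of participant videos this method targets are not publicly
available, the package ships a synthetic gait generator — a 25-keypoint
stick body on a pinhole-projected 5 m walk with controllable heading skew,
pixel jitter and detection dropout — which is the substrate for all tests.

## Worked example

```r
library(skewgait)

# one synthetic walk: 3 degrees of leftward heading skew, receding camera view
w <- generate_walk(walker_params(skew_deg = 3, noise_sd_px = 1, seed = 11),
                   direction = "away", label = "skew_left")
w
#> <pose_sequence> 221 frames @ 30 fps (7.37 s), subject 'sim', away, label 'skew_left'

fit_tsr(extract_isoblock(sample_frames(w, 0.3)))
#>   lt: alpha =   3770.492  beta =  -3.5593  sd =   3.634  (n = 25)
#>   rt: alpha =   -981.937  beta =   1.6768  sd =   2.101  (n = 25)
#>   lb: alpha =  -4248.733  beta =   5.2758  sd =   5.400  (n = 25)
#>   rb: alpha =   2796.128  beta =  -2.4859  sd =   2.484  (n = 25)

walk_features(w)
#> <gait_features> TAR = 1.2554  BAR = 1.1642  velocity = 0.694 m/s
```

Both ratios sit above 1, as they must for a left-veering walker; velocity
recovers the simulated 0.68 m/s within 2%.

```r
# a 210-sample low-noise feature cohort on the published scale, classified
feats <- simulate_features(seed = 1)
train_svm_cv(feats[, c("tar", "bar", "velocity_mps")], feats$label,
             folds = 10, seed = 1)
#> 10-fold CV: accuracy = 0.995, kappa = 0.992
#>             predicted
#> truth        skew_left skew_right straight
#>   skew_left         36          0        0
#>   skew_right         0         88        1
#>   straight           0          0       85

roc_analysis(feats$tar[feats$label == "straight"],
             feats$tar[feats$label == "skew_left"])
#> ROC: AUC = 1.0000 (p = 4.156e-18), CP = 1.0259, greater_indicates_positive
```

The cutting point 1.026 is the TAR threshold above which this synthetic
cohort's walks are flagged as left-skewed.

## Command line

An executable wrapper is installed at `exec/skewgait` inside the package
(or call `skewgait_cli()` directly):

```sh
skewgait simulate --out walks/ --subjects 35 --walks 6 --seed 7
skewgait features --in walks/ --interval 0.3 --out features.csv
skewgait classify --features features.csv --folds 10 --report report.json
skewgait roc --features features.csv --positive skew_left --feature tar --out roc.json
skewgait run --out run1/ --seed 7        # full pipeline in one step
```

Exit codes: 0 success, 2 validation error, 1 stage failure.

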