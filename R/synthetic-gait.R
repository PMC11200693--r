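# Synthetic walker: a 25-keypoint stick body on a straight (or skewed) heading
# along a flat path, filmed by a static pinhole camera 1 m above the floor and
# 2 m from the near end of a 5 m path. Emulates the recording protocol the
# feature pipeline expects, with perspective scaling, sinusoidal limb swing,
# Gaussian pixel jitter and confidence-0 dropout.

# Body template in the walker's own frame: column 1 = lateral offset toward
# the walker's LEFT (metres), column 2 = height above floor (metres).
# Rows follow BODY_25 order.
body_template <- function() {
  m <- matrix(c(
     0.00, 1.62,   # Nose
     0.00, 1.43,   # Neck
    -0.23, 1.43,   # RShoulder
    -0.27, 1.18,   # RElbow
    -0.29, 0.95,   # RWrist
     0.23, 1.43,   # LShoulder
     0.27, 1.18,   # LElbow
     0.29, 0.95,   # LWrist
     0.00, 0.95,   # MidHip
    -0.12, 0.95,   # RHip
    -0.13, 0.52,   # RKnee
    -0.14, 0.08,   # RAnkle
     0.12, 0.95,   # LHip
     0.13, 0.52,   # LKnee
     0.14, 0.08,   # LAnkle
    -0.04, 1.66,   # REye
     0.04, 1.66,   # LEye
    -0.08, 1.62,   # REar
     0.08, 1.62,   # LEar
     0.15, 0.02,   # LBigToe
     0.18, 0.02,   # LSmallToe
     0.13, 0.03,   # LHeel
    -0.15, 0.02,   # RBigToe
    -0.18, 0.02,   # RSmallToe
    -0.13, 0.03    # RHeel
  ), ncol = 2, byrow = TRUE)
  rownames(m) <- body25_joints()
  m
}

# joints whose depth is modulated by gait phase (leg pair / arm pair)
LEFT_LEG  <- c("LKnee", "LAnkle", "LBigToe", "LSmallToe", "LHeel")
RIGHT_LEG <- c("RKnee", "RAnkle", "RBigToe", "RSmallToe", "RHeel")
LEFT_ARM  <- c("LElbow", "LWrist")
RIGHT_ARM <- c("RElbow", "RWrist")

#' Parameters of a synthetic walk
#'
#' @param skew_deg Heading offset in degrees in the walker's body frame:
#'   0 walks straight along the path; positive values drift toward the
#'   walker's own left, negative toward their right. (A walker who veers left
#'   drifts to the viewer's right when approaching the camera and to the
#'   viewer's left when receding; defining skew in the body frame keeps the
#'   slope-angle ratios on the same side of 1 for both legs of a round trip.)
#' @param speed_mps Walking speed in metres/second.
#' @param duration_s Walk duration; defaults to `path_length_m / speed_mps`.
#' @param fps Camera frame rate.
#' @param noise_sd_px Standard deviation of i.i.d. Gaussian pixel jitter added
#'   to every projected keypoint coordinate.
#' @param dropout_rate Per-keypoint probability of a missed detection
#'   (confidence set to 0); must be < 1.
#' @param seed Integer RNG seed; a walk is bit-reproducible given its seed.
#' @param image_size `c(width, height)` of the camera image in pixels.
#' @param start_distance_m Camera distance to the near end of the path
#'   (metres); the walker occupies depths `start_distance_m` to
#'   `start_distance_m + path_length_m`.
#' @param path_length_m Path length in metres.
#' @param focal_px Pinhole focal constant in pixels.
#' @param camera_height_m Camera height above the floor.
#' @param stride_m Stride length driving the limb-swing phase.
#' @return A `walker_params` list.
#' @export
walker_params <- function(skew_deg = 0, speed_mps = 0.68, duration_s = NULL,
                          fps = 30, noise_sd_px = 0, dropout_rate = 0,
                          seed = 1L, image_size = c(1920, 1080),
                          start_distance_m = 2, path_length_m = 5,
                          focal_px = 1000, camera_height_m = 1,
                          stride_m = 1) {
  if (speed_mps <= 0) stop("`speed_mps` must be > 0")
  if (fps <= 0) stop("`fps` must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("`dropout_rate` must be in [0, 1)")
  if (noise_sd_px < 0) stop("`noise_sd_px` must be >= 0")
  if (is.null(duration_s)) duration_s <- path_length_m / speed_mps
  structure(list(skew_deg = skew_deg, speed_mps = speed_mps,
                 duration_s = duration_s, fps = fps,
                 noise_sd_px = noise_sd_px, dropout_rate = dropout_rate,
                 seed = as.integer(seed), image_size = image_size,
                 start_distance_m = start_distance_m,
                 path_length_m = path_length_m, focal_px = focal_px,
                 camera_height_m = camera_height_m, stride_m = stride_m),
            class = "walker_params")
}

#' Generate one synthetic walk
#'
#' Places the stick-body template at a per-frame world position (depth runs
#' from far to near for `"toward"` walks and near to far for `"away"` walks;
#' lateral offset grows as `tan(skew) * distance walked`), modulates limb
#' depths sinusoidally with the stride phase, projects through a pinhole
#' camera, then applies Gaussian pixel jitter and confidence dropout.
#'
#' @param params A [walker_params()] object.
#' @param direction `"toward"` (approaching the camera) or `"away"`.
#' @param label Group label to attach (`"straight"`, `"skew_left"`,
#'   `"skew_right"`, `"unlabeled"`).
#' @param subject_id Subject identifier stored on the sequence.
#' @return A [pose_sequence()] in image-convention pixel coordinates.
#' @export
generate_walk <- function(params, direction = c("toward", "away"),
                          label = "unlabeled", subject_id = "sim") {
  direction <- match.arg(direction)
  stopifnot(inherits(params, "walker_params"))
  p <- params

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(p$seed)

  n <- max(2L, as.integer(round(p$duration_s * p$fps)))
  t <- (seq_len(n) - 1) / p$fps
  dist_walked <- pmin(p$speed_mps * t, p$path_length_m)
  depth_c <- if (direction == "away") p$start_distance_m + dist_walked
             else p$start_distance_m + p$path_length_m - dist_walked

  # walker's left axis in world x (viewer's right = +x):
  # facing the camera, the walker's left is the viewer's right
  lat_sign <- if (direction == "toward") 1 else -1
  lateral_c <- lat_sign * tan(p$skew_deg * pi / 180) * dist_walked

  tmpl <- body_template()
  jn <- rownames(tmpl)
  phase <- 2 * pi * (p$speed_mps / p$stride_m) * t

  w <- p$image_size[1]; h <- p$image_size[2]
  cx <- w / 2; cy <- h / 2
  coords <- array(0, dim = c(n, N_JOINTS, 3))

  # Limb swing is modelled as vertical modulation (swing-foot lift, arm
  # pump), anti-phase between left and right. Keeping the modulation in y,
  # with all joints at the body-centre depth, preserves exact left-right
  # mirror symmetry of each projected frame: a straight walk has constant
  # bounding-box centre x and a strictly perspective-driven box height.
  dy <- matrix(0, n, N_JOINTS, dimnames = list(NULL, jn))
  lift_l <- 0.08 * pmax(0, sin(phase))
  lift_r <- 0.08 * pmax(0, -sin(phase))
  dy[, LEFT_LEG]  <- lift_l
  dy[, RIGHT_LEG] <- lift_r
  dy[, "LKnee"]   <- 0.5 * lift_l
  dy[, "RKnee"]   <- 0.5 * lift_r
  dy[, LEFT_ARM]  <-  0.04 * sin(phase)
  dy[, RIGHT_ARM] <- -0.04 * sin(phase)

  for (i in seq_len(n)) {
    x_w <- lat_sign * tmpl[, 1] + lateral_c[i]
    y_w <- tmpl[, 2] + dy[i, ]
    s <- p$focal_px / depth_c[i]
    u <- cx + x_w * s
    v <- cy - (y_w - p$camera_height_m) * s
    coords[i, , 1] <- u
    coords[i, , 2] <- v
  }

  # fraction of frames whose body box leaves the image
  out <- vapply(seq_len(n), function(i) {
    u <- coords[i, , 1]; v <- coords[i, , 2]
    any(u < 0 | u > w | v < 0 | v > h)
  }, logical(1))
  if (mean(out) > 0.2)
    stop(sprintf(paste("walker projects outside the image in %.0f%% of frames;",
                       "reduce |skew_deg|, increase start_distance_m, or enlarge",
                       "image_size"), 100 * mean(out)))

  if (p$noise_sd_px > 0) {
    coords[, , 1] <- coords[, , 1] + rnorm(n * N_JOINTS, sd = p$noise_sd_px)
    coords[, , 2] <- coords[, , 2] + rnorm(n * N_JOINTS, sd = p$noise_sd_px)
  }
  conf <- matrix(runif(n * N_JOINTS, 0.6, 0.99), n, N_JOINTS)
  if (p$dropout_rate > 0) {
    drop <- matrix(runif(n * N_JOINTS) < p$dropout_rate, n, N_JOINTS)
    conf[drop] <- 0
  }
  coords[, , 3] <- conf

  pose_sequence(coords, fps = p$fps, subject_id = subject_id,
                direction = direction, label = label,
                path_length_m = p$path_length_m)
}

#' Specification of a synthetic cohort
#'
#' Defaults mirror the recording protocol the pipeline is calibrated to:
#' 35 subjects each filmed on 3 round trips of a 5 m path (6 walks), with the
#' skewed groups sized at roughly 17% (left) and 42% (right) of subjects.
#'
#' @param n_subjects Number of subjects.
#' @param walks_per_subject Walks per subject; directions alternate
#'   away/toward so 6 walks form 3 round trips.
#' @param frac_left,frac_right Fractions of subjects assigned to the
#'   skew-left / skew-right groups; the remainder walk straight.
#' @param skew_range_deg Range of |heading offset| degrees drawn uniformly per
#'   skewed subject.
#' @param speed_mean_mps,speed_sd_mps Per-subject walking-speed distribution.
#' @param noise_sd_px,dropout_rate Keypoint jitter and dropout applied to
#'   every walk.
#' @param fps Camera frame rate.
#' @param seed Cohort RNG seed; each walk gets its own derived stream.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 35, walks_per_subject = 6,
                        frac_left = 36 / 210, frac_right = 89 / 210,
                        skew_range_deg = c(1.5, 4),
                        speed_mean_mps = 0.68, speed_sd_mps = 0.04,
                        noise_sd_px = 2, dropout_rate = 0.02,
                        fps = 30, seed = 1L) {
  if (n_subjects < 1 || walks_per_subject < 1)
    stop("`n_subjects` and `walks_per_subject` must be >= 1")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a labeled synthetic cohort
#'
#' Assigns each subject to a group (straight / skew-left / skew-right, counts
#' rounded from the [cohort_spec()] fractions), draws a per-subject speed and
#' skew magnitude, and generates `walks_per_subject` walks with alternating
#' direction. Reproducible from the cohort seed; each walk has an independent
#' derived RNG stream.
#'
#' @param spec A [cohort_spec()].
#' @return A list of [pose_sequence()] objects of length
#'   `n_subjects * walks_per_subject`, each carrying subject id, direction and
#'   group label.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  ns <- spec$n_subjects
  n_left <- round(spec$frac_left * ns)
  n_right <- round(spec$frac_right * ns)
  if (n_left + n_right > ns) stop("group fractions exceed 1")
  groups <- sample(c(rep("skew_left", n_left), rep("skew_right", n_right),
                     rep("straight", ns - n_left - n_right)))
  speeds <- pmax(0.3, rnorm(ns, spec$speed_mean_mps, spec$speed_sd_mps))
  mags <- runif(ns, spec$skew_range_deg[1], spec$skew_range_deg[2])
  walk_seeds <- matrix(sample.int(.Machine$integer.max,
                                  ns * spec$walks_per_subject),
                       ns, spec$walks_per_subject)

  out <- vector("list", ns * spec$walks_per_subject)
  k <- 0L
  for (s in seq_len(ns)) {
    skew <- switch(groups[s], straight = 0, skew_left = mags[s],
                   skew_right = -mags[s])
    for (wk in seq_len(spec$walks_per_subject)) {
      dirn <- if (wk %% 2L == 1L) "away" else "toward"
      p <- walker_params(skew_deg = skew, speed_mps = speeds[s],
                         fps = spec$fps, noise_sd_px = spec$noise_sd_px,
                         dropout_rate = spec$dropout_rate,
                         seed = walk_seeds[s, wk])
      k <- k + 1L
      out[[k]] <- generate_walk(p, direction = dirn, label = groups[s],
                                subject_id = sprintf("S%02d", s))
      attr(out[[k]], "walk") <- wk
    }
  }
  out
}

#' Simulate gait features at the group level
#'
#' Draws `(TAR, BAR, velocity)` triples directly from per-group Gaussian
#' distributions, bypassing the image pipeline. The default group means are
#' the published-scale calibration template the package targets (straight
#' near 1, left-skew above 1, right-skew below 1); `sd_scale` shrinks the
#' printed dispersions to emulate a low-noise recording.
#'
#' @param n Named integer vector of group sizes
#'   (`straight`, `skew_left`, `skew_right`).
#' @param tar_mean,bar_mean,vel_mean Group means in the order straight, left,
#'   right.
#' @param tar_sd,bar_sd,vel_sd Group standard deviations (same order).
#' @param sd_scale Multiplier applied to all standard deviations. The
#'   default 0.18 is calibrated so the Bayes accuracy of the resulting
#'   three-class Gaussian mixture (computed by Monte Carlo from the known
#'   densities and group priors) equals 0.990, the published-scale
#'   classification accuracy this low-noise world emulates.
#' @param seed RNG seed.
#' @return A data.frame with columns `tar`, `bar`, `velocity_mps`, `label`.
#' @export
simulate_features <- function(n = c(straight = 85, skew_left = 36, skew_right = 89),
                              tar_mean = c(0.952, 1.121, 0.847),
                              bar_mean = c(0.965, 1.057, 0.918),
                              vel_mean = c(0.676, 0.684, 0.694),
                              tar_sd = c(0.147, 0.196, 0.175),
                              bar_sd = c(0.122, 0.105, 0.101),
                              vel_sd = c(0.072, 0.085, 0.079),
                              sd_scale = 0.18, seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  grp <- c("straight", "skew_left", "skew_right")
  out <- do.call(rbind, lapply(seq_along(grp), function(g) {
    ng <- n[[grp[g]]]
    data.frame(
      tar = rnorm(ng, tar_mean[g], tar_sd[g] * sd_scale),
      bar = rnorm(ng, bar_mean[g], bar_sd[g] * sd_scale),
      velocity_mps = rnorm(ng, vel_mean[g], vel_sd[g] * sd_scale),
      label = grp[g])
  }))
  rownames(out) <- NULL
  out
}
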