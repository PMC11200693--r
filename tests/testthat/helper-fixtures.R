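# Fixtures are built in code; no data files.

# A pose sequence with all 25 keypoints placed on a small ring around a
# per-frame centre, fully confident unless stated.
make_seq <- function(centres_x, centres_y, fps = 30, conf = 1, radius = 5,
                     ...) {
  n <- length(centres_x)
  theta <- seq(0, 2 * pi, length.out = 26)[1:25]
  coords <- array(0, dim = c(n, 25, 3))
  for (i in seq_len(n)) {
    coords[i, , 1] <- centres_x[i] + radius * cos(theta)
    coords[i, , 2] <- centres_y[i] + radius * sin(theta)
  }
  coords[, , 3] <- conf
  pose_sequence(coords, fps = fps, ...)
}

# Fully random (but valid) sequence for fuzz/round-trip tests.
random_seq <- function(n = 4, fps = 30, seed = 1) {
  set.seed(seed)
  coords <- array(0, dim = c(n, 25, 3))
  coords[, , 1] <- runif(n * 25, 0, 1920)
  coords[, , 2] <- runif(n * 25, 0, 1080)
  coords[, , 3] <- round(runif(n * 25), 6)
  pose_sequence(coords, fps = fps, subject_id = paste0("fuzz", seed))
}

# Write one OpenPose-style JSON file per frame of `seq` into `dir`.
write_openpose_dir <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n_frames(seq))
  for (i in seq_len(n_frames(seq))) {
    flat <- as.vector(t(seq$coords[i, , ]))
    rec <- list(version = 1.3,
                people = list(list(pose_keypoints_2d = flat)))
    paths[i] <- file.path(dir, sprintf("frame_%06d_keypoints.json", i - 1))
    jsonlite::write_json(rec, paths[i], auto_unbox = TRUE, digits = NA)
  }
  paths
}

# Reflect a sequence left-right about the vertical image centreline.
mirror_seq <- function(seq, width = 1920) {
  coords <- seq$coords
  coords[, , 1] <- width - coords[, , 1]
  pose_sequence(coords, fps = seq$fps, frame_index = seq$frame_index,
                subject_id = seq$subject_id, direction = seq$direction,
                label = seq$label, path_length_m = seq$path_length_m)
}

# Closed-form normal-equations simple linear regression (independent oracle).
ols_oracle <- function(x, y) {
  n <- length(x)
  beta <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  alpha <- mean(y) - beta * mean(x)
  c(alpha = alpha, beta = beta)
}

# Brute-force pair-counting AUC (ties count one half), positive = b.
auc_pairs_oracle <- function(a, b) {
  s <- outer(b, a, function(bb, aa) (bb > aa) + 0.5 * (bb == aa))
  mean(s)
}
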