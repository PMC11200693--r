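#' BODY_25 joint names
#'
#' Joint names of the 25-keypoint body model used by common markerless pose
#' estimators, in index order 0--24. Index `i` of the model corresponds to
#' element `i + 1` of this vector.
#'
#' @return Character vector of length 25.
#' @export
body25_joints <- function() {
  c("Nose", "Neck",
    "RShoulder", "RElbow", "RWrist",
    "LShoulder", "LElbow", "LWrist",
    "MidHip", "RHip", "RKnee", "RAnkle",
    "LHip", "LKnee", "LAnkle",
    "REye", "LEye", "REar", "LEar",
    "LBigToe", "LSmallToe", "LHeel",
    "RBigToe", "RSmallToe", "RHeel")
}

N_JOINTS <- 25L

#' Construct a pose sequence
#'
#' A pose sequence is the raw input of every pipeline stage: an ordered set of
#' video frames, each carrying the 25 BODY_25 keypoints as `(x, y, confidence)`
#' triplets. Coordinates are 0-based pixels in image convention (y grows
#' downward); a keypoint with `confidence == 0` is missing and its coordinates
#' carry no meaning. Any axis flip to Cartesian convention happens downstream
#' in the feature stage, never at I/O.
#'
#' @param coords Numeric array `n_frames x 25 x 3`; the third margin is
#'   `(x, y, confidence)`.
#' @param fps Frames per second of the source video (> 0).
#' @param frame_index Integer vector of source frame indices (strictly
#'   increasing, >= 0). Defaults to `0:(n_frames - 1)`.
#' @param subject_id Opaque subject identifier.
#' @param direction `"toward"` or `"away"` (relative to the camera).
#' @param label Group label: `"straight"`, `"skew_left"`, `"skew_right"` or
#'   `"unlabeled"`.
#' @param path_length_m Known walked path length in metres (default 5).
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(coords, fps,
                          frame_index = NULL,
                          subject_id = "unknown",
                          direction = c("toward", "away"),
                          label = c("unlabeled", "straight", "skew_left", "skew_right"),
                          path_length_m = 5) {
  direction <- match.arg(direction)
  label <- match.arg(label)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a single positive number")
  if (path_length_m <= 0) stop("`path_length_m` must be > 0")
  if (length(dim(coords)) != 3L || dim(coords)[2] != N_JOINTS || dim(coords)[3] != 3L)
    stop("`coords` must be an n_frames x 25 x 3 array")
  n <- dim(coords)[1]
  if (is.null(frame_index)) frame_index <- seq_len(n) - 1L
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != n) stop("`frame_index` length must match frames")
  if (n > 1L && any(diff(frame_index) <= 0L))
    stop("`frame_index` must be strictly increasing")
  if (any(frame_index < 0L)) stop("`frame_index` must be >= 0")
  conf <- coords[, , 3, drop = FALSE]
  if (any(conf < 0 | conf > 1)) stop("confidences must lie in [0, 1]")
  dimnames(coords) <- list(NULL, body25_joints(), c("x", "y", "confidence"))
  structure(list(
    coords = coords,
    frame_index = frame_index,
    timestamp = frame_index / fps,
    fps = fps,
    subject_id = as.character(subject_id),
    direction = direction,
    label = label,
    path_length_m = path_length_m
  ), class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf(
    "<pose_sequence> %d frames @ %g fps (%.2f s), subject '%s', %s, label '%s'\n",
    n_frames(x), x$fps, duration_s(x), x$subject_id, x$direction, x$label))
  vis <- mean(x$coords[, , 3] > 0)
  cat(sprintf("  keypoints visible: %.1f%%; path length %g m\n", 100 * vis,
              x$path_length_m))
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param seq A `pose_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$coords)[1]

#' Duration of a pose sequence in seconds
#'
#' Defined as last timestamp plus one frame period, i.e. the length of video
#' the frames span.
#'
#' @param seq A `pose_sequence`.
#' @return Duration in seconds.
#' @export
duration_s <- function(seq) {
  n <- n_frames(seq)
  if (n == 0L) return(0)
  seq$timestamp[n] + 1 / seq$fps
}

# Subset frames by position (1-based), keeping metadata.
subset_frames <- function(seq, idx) {
  pose_sequence(seq$coords[idx, , , drop = FALSE], fps = seq$fps,
                frame_index = seq$frame_index[idx],
                subject_id = seq$subject_id, direction = seq$direction,
                label = seq$label, path_length_m = seq$path_length_m)
}
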