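# Feature core: per sampled frame, the axis-aligned bounding box of the
# confident keypoints ("iso-block"); across frames, four ordinary
# least-squares lines through the four corner trajectories; per walk, the
# ratios of the sign-adjusted arctangents of the top and bottom slopes
# (TAR, BAR) plus walking velocity.

#' Extract the iso-block corner series from a sampled sequence
#'
#' For each frame, the axis-aligned bounding box of keypoints above the
#' confidence threshold, reported in Cartesian convention (y flipped:
#' `y_cart = image_height - y_image`, so y grows upward). Corners are
#' left-top (lt), right-top (rt), left-bottom (lb), right-bottom (rb); lt/lb
#' share `x_min`, rt/rb share `x_max`, lt/rt share `y_max`, lb/rb share
#' `y_min`. Frames with fewer than 2 confident keypoints or a zero-area box
#' are dropped with a warning; more than 50% dropped is an error.
#'
#' @param seq A sampled [pose_sequence()].
#' @param conf_threshold Minimum keypoint confidence.
#' @param image_height Source image height in pixels (for the y flip).
#' @return An `isoblock_series`: data.frame with columns `frame_index`,
#'   `timestamp`, `x_lt`, `y_lt`, `x_rt`, `y_rt`, `x_lb`, `y_lb`, `x_rb`,
#'   `y_rb`; attributes `n_dropped` and `image_height`.
#' @export
extract_isoblock <- function(seq, conf_threshold = 0.1, image_height = 1080) {
  boxes <- frame_boxes(seq, conf_threshold)
  ok <- stats::complete.cases(boxes)
  n_drop <- sum(!ok)
  if (n_drop > 0)
    warning(sprintf("dropped %d frame(s) without a valid iso-block", n_drop))
  if (n_drop > 0.5 * nrow(boxes))
    stop(sprintf("more than half the frames (%d of %d) lack a valid iso-block",
                 n_drop, nrow(boxes)))
  b <- boxes[ok, , drop = FALSE]
  out <- data.frame(
    frame_index = seq$frame_index[ok],
    timestamp = seq$timestamp[ok],
    x_lt = b$x_min, y_lt = image_height - b$y_min,
    x_rt = b$x_max, y_rt = image_height - b$y_min,
    x_lb = b$x_min, y_lb = image_height - b$y_max,
    x_rb = b$x_max, y_rb = image_height - b$y_max)
  attr(out, "n_dropped") <- n_drop
  attr(out, "image_height") <- image_height
  class(out) <- c("isoblock_series", "data.frame")
  out
}

CORNERS <- c("lt", "rt", "lb", "rb")

#' Fit the four temporal-spatial regression models
#'
#' Per corner, ordinary least squares of the corner's vertical position on
#' its horizontal position across sampled frames:
#' `y_c,i = alpha_c + beta_c * x_c,i + eps_c,i` for corner
#' `c` in lt, rt, lb, rb. The slope's arctangent is the angle between the
#' corner's trajectory and the x-axis.
#'
#' @param series An [extract_isoblock()] result with at least 3 frames.
#' @return A `tsr_fits` object: named list (lt, rt, lb, rb) of lists with
#'   `corner`, `alpha` (intercept, px), `beta` (slope), `residual_sd` (px)
#'   and `n`.
#' @export
fit_tsr <- function(series) {
  n <- nrow(series)
  if (n < 3L) stop("need at least 3 frames to fit the corner regressions")
  fits <- lapply(CORNERS, function(cn) {
    x <- series[[paste0("x_", cn)]]
    y <- series[[paste0("y_", cn)]]
    if (max(x) == min(x))
      stop(sprintf("degenerate trajectory for corner '%s': zero x-variance", cn))
    fit <- stats::.lm.fit(cbind(1, x), y)
    co <- fit$coefficients
    rsd <- if (n > 2) sqrt(sum(fit$residuals^2) / (n - 2)) else 0
    list(corner = cn, alpha = co[1], beta = co[2], residual_sd = rsd, n = n)
  })
  names(fits) <- CORNERS
  class(fits) <- "tsr_fits"
  fits
}

#' @export
print.tsr_fits <- function(x, ...) {
  for (f in x)
    cat(sprintf("  %s: alpha = %10.3f  beta = %8.4f  sd = %7.3f  (n = %d)\n",
                f$corner, f$alpha, f$beta, f$residual_sd, f$n))
  invisible(x)
}

sign_beta <- function(beta) ifelse(beta < 0, -1, 1)

#' Compute the top and bottom slope-angle ratios (TAR, BAR)
#'
#' `TAR = sign(beta_lt) atan(beta_lt) / (sign(beta_rt) atan(beta_rt))` and
#' `BAR` analogously for the bottom corners, with `sign(b) = -1` if `b < 0`
#' and `+1` otherwise (so `sign(0) = +1`). Each term equals the magnitude of
#' the angle between the corner regression line and the x-axis, so both
#' ratios are nonnegative and unit-free (radians cancel). Straight walking
#' yields ratios near 1; a walker skewing to their left pushes both above 1,
#' to their right below 1. A zero denominator angle marks the feature invalid
#' rather than raising an error.
#'
#' @param fits A [fit_tsr()] result.
#' @return A `gait_features` list: `tar`, `bar`, `velocity_mps` (NA here;
#'   see [compute_velocity()]), `valid`, `reason`.
#' @export
compute_tar_bar <- function(fits) {
  stopifnot(inherits(fits, "tsr_fits"))
  ang <- function(b) sign_beta(b) * atan(b)
  a_lt <- ang(fits$lt$beta); a_rt <- ang(fits$rt$beta)
  a_lb <- ang(fits$lb$beta); a_rb <- ang(fits$rb$beta)
  valid <- TRUE; reason <- NA_character_
  tar <- bar <- NA_real_
  if (a_rt == 0 || a_rb == 0) {
    valid <- FALSE
    reason <- sprintf("zero denominator angle (beta_rt = %g, beta_rb = %g)",
                      fits$rt$beta, fits$rb$beta)
  } else {
    tar <- a_lt / a_rt
    bar <- a_lb / a_rb
  }
  structure(list(tar = tar, bar = bar, velocity_mps = NA_real_,
                 valid = valid, reason = reason),
            class = "gait_features")
}

#' @export
print.gait_features <- function(x, ...) {
  if (x$valid)
    cat(sprintf("<gait_features> TAR = %.4f  BAR = %.4f  velocity = %s m/s\n",
                x$tar, x$bar,
                ifelse(is.na(x$velocity_mps), "NA",
                       sprintf("%.3f", x$velocity_mps))))
  else
    cat(sprintf("<gait_features> invalid: %s\n", x$reason))
  invisible(x)
}

#' Compute walking velocity from the known path length
#'
#' The walk covers a known path length; velocity is that length divided by
#' the traversal time, taken as the span between the first and last frame
#' carrying a valid iso-block.
#'
#' @param seq A [pose_sequence()] with `path_length_m` set.
#' @param series Optional [extract_isoblock()] result; when supplied, only
#'   its frames define the time span.
#' @return Velocity in metres/second.
#' @export
compute_velocity <- function(seq, series = NULL) {
  ts <- if (is.null(series)) seq$timestamp else series$timestamp
  span <- max(ts) - min(ts)
  if (span <= 0) stop("zero traversal time")
  seq$path_length_m / span
}

#' Full per-walk feature extraction
#'
#' Convenience wrapper: sample, extract the iso-block, fit the four corner
#' regressions and return TAR, BAR and velocity for one walk.
#'
#' @param seq An unsampled [pose_sequence()].
#' @param interval_s Sampling interval in seconds.
#' @param conf_threshold Minimum keypoint confidence.
#' @param image_height Source image height in pixels.
#' @return A `gait_features` list with `tar`, `bar`, `velocity_mps`, `valid`,
#'   `reason`, plus `n_frames` (sampled frames used).
#' @export
walk_features <- function(seq, interval_s = 0.3, conf_threshold = 0.1,
                          image_height = 1080) {
  s <- sample_frames(seq, interval_s)
  series <- extract_isoblock(s, conf_threshold, image_height)
  fits <- fit_tsr(series)
  feat <- compute_tar_bar(fits)
  feat$velocity_mps <- compute_velocity(seq, series)
  feat$n_frames <- nrow(series)
  feat
}

#' Feature table for a list of walks
#'
#' Applies [walk_features()] to every sequence, collecting a tidy table.
#' Walks whose feature extraction fails outright (degenerate boxes) are kept
#' with `valid = FALSE` and the error message as `reason`.
#'
#' @param walks List of [pose_sequence()] objects.
#' @param interval_s,conf_threshold,image_height Passed to [walk_features()].
#' @return data.frame with columns `subject`, `walk`, `direction`, `label`,
#'   `tar`, `bar`, `velocity_mps`, `valid`, `reason`, `n_frames`.
#' @export
cohort_features <- function(walks, interval_s = 0.3, conf_threshold = 0.1,
                            image_height = 1080) {
  rows <- lapply(seq_along(walks), function(i) {
    w <- walks[[i]]
    wk <- attr(w, "walk") %||% i
    f <- tryCatch(
      suppressWarnings(walk_features(w, interval_s, conf_threshold, image_height)),
      error = function(e) list(tar = NA_real_, bar = NA_real_,
                               velocity_mps = NA_real_, valid = FALSE,
                               reason = conditionMessage(e), n_frames = NA_integer_))
    data.frame(subject = w$subject_id, walk = wk, direction = w$direction,
               label = w$label, tar = f$tar, bar = f$bar,
               velocity_mps = f$velocity_mps, valid = f$valid,
               reason = if (is.null(f$reason) || is.na(f$reason)) "" else f$reason,
               n_frames = f$n_frames)
  })
  do.call(rbind, rows)
}
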