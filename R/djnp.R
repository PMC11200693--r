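# Dynamic joint-node plots: a walk is summarised as one image by dropping a
# unit-mass isotropic Gaussian at every confident keypoint of every sampled
# frame and summing. Merging is additive so total grid mass counts the
# contributing keypoints, which gives the conservation property the tests
# lean on.

#' Build a dynamic joint-node plot
#'
#' @param seq A sampled [pose_sequence()] (apply [sample_frames()] first; the
#'   function does not resample).
#' @param sigma_px Gaussian kernel standard deviation in source-image pixels.
#' @param downscale Integer factor by which the source image is downscaled to
#'   form the accumulation grid (1920x1080 at the default 4 gives 480x270).
#' @param conf_threshold Keypoints at or below this confidence are ignored.
#' @param image_size `c(width, height)` of the source image in pixels.
#' @return A `djnp` object: list with `grid` (height x width matrix of
#'   accumulated intensity), `sigma_px`, `downscale`, `n_frames_merged`,
#'   `n_keypoints`, `extent`.
#' @details Each kernel is normalised to unit mass over its own truncated
#'   window (radius 4 sigma), then clipped at grid edges without
#'   renormalisation; kernels fully inside the grid therefore contribute
#'   exactly 1 to the total mass.
#' @export
build_djnp <- function(seq, sigma_px = 3, downscale = 4, conf_threshold = 0.1,
                       image_size = c(1920, 1080)) {
  if (sigma_px <= 0) stop("`sigma_px` must be > 0")
  if (downscale < 1) stop("`downscale` must be >= 1")
  n <- n_frames(seq)
  if (n == 0L) stop("empty sequence")
  gw <- ceiling(image_size[1] / downscale)
  gh <- ceiling(image_size[2] / downscale)
  grid <- matrix(0, nrow = gh, ncol = gw)

  sg <- sigma_px / downscale
  r <- ceiling(4 * sg)
  off <- (-r):r
  g1 <- exp(-off^2 / (2 * sg^2))
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)

  vis <- seq$coords[, , 3, drop = FALSE] > conf_threshold
  total <- sum(vis)
  if (total == 0L) stop("empty DJNP: no keypoint above the confidence threshold")

  for (i in seq_len(n)) {
    for (j in seq_len(N_JOINTS)) {
      if (!vis[i, j, 1]) next
      # grid cell of the keypoint (1-based; cell k covers source pixels
      # [(k-1)*downscale, k*downscale))
      cxg <- floor(seq$coords[i, j, 1] / downscale) + 1
      cyg <- floor(seq$coords[i, j, 2] / downscale) + 1
      rows <- cyg + off
      cols <- cxg + off
      rok <- rows >= 1 & rows <= gh
      cok <- cols >= 1 & cols <= gw
      if (!any(rok) || !any(cok)) next
      grid[rows[rok], cols[cok]] <- grid[rows[rok], cols[cok]] +
        kern[rok, cok, drop = FALSE]
    }
  }
  structure(list(grid = grid, sigma_px = sigma_px, downscale = downscale,
                 n_frames_merged = n, n_keypoints = total,
                 extent = image_size),
            class = "djnp")
}

#' @export
print.djnp <- function(x, ...) {
  cat(sprintf("<djnp> %dx%d grid (downscale %g, sigma %g px), %d frames, mass %.2f\n",
              ncol(x$grid), nrow(x$grid), x$downscale, x$sigma_px,
              x$n_frames_merged, sum(x$grid)))
  invisible(x)
}

#' Export a DJNP as a PNG image
#'
#' Intensities are rank-normalised to \[0, 1\] and rendered with a
#' viridis-style palette.
#'
#' @param djnp A [build_djnp()] result.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
djnp_png <- function(djnp, path) {
  g <- djnp$grid
  z <- t(g[nrow(g):1, , drop = FALSE])  # image() wants x-right, y-up
  grDevices::png(path, width = ncol(g), height = nrow(g))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::image(z, col = grDevices::hcl.colors(256, "viridis"),
                  axes = FALSE, useRaster = TRUE)
  invisible(path)
}

#' Export a DJNP as a plain-text array with a JSON sidecar
#'
#' Writes the grid as TSV (one row per grid row) plus `<path>.json` recording
#' sigma, downscale, frame count and extent.
#'
#' @param djnp A [build_djnp()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
djnp_write <- function(djnp, path) {
  utils::write.table(djnp$grid, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(sigma_px = djnp$sigma_px,
                            downscale = djnp$downscale,
                            n_frames_merged = djnp$n_frames_merged,
                            n_keypoints = djnp$n_keypoints,
                            extent = djnp$extent),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Sampling-sufficiency score of a frame interval
#'
#' Diagnoses whether a sampling interval is fine enough for consecutive body
#' silhouettes to overlap in the merged plot. For each consecutive pair of
#' sampled frames the overlap score is `max(0, 1 - gap / width)` where `gap`
#' is the distance between the two bounding-box centres and `width` the mean
#' of the two box widths; the result is the mean over pairs. 1 means heavily
#' overlapping silhouettes, 0 disjoint ones.
#'
#' @param seq A [pose_sequence()] (unsampled).
#' @param interval_s Sampling interval in seconds passed to [sample_frames()].
#' @param conf_threshold Minimum keypoint confidence for the bounding boxes.
#' @return Coverage score in \[0, 1\].
#' @export
sampling_sufficiency <- function(seq, interval_s, conf_threshold = 0.1) {
  s <- sample_frames(seq, interval_s)
  if (n_frames(s) < 2L) stop("fewer than 2 sampled frames")
  boxes <- frame_boxes(s, conf_threshold)
  ok <- stats::complete.cases(boxes)
  boxes <- boxes[ok, , drop = FALSE]
  if (nrow(boxes) < 2L) stop("fewer than 2 sampled frames with a valid box")
  cx <- (boxes$x_min + boxes$x_max) / 2
  cy <- (boxes$y_min + boxes$y_max) / 2
  wd <- boxes$x_max - boxes$x_min
  gap <- sqrt(diff(cx)^2 + diff(cy)^2)
  width <- (wd[-1] + wd[-length(wd)]) / 2
  mean(pmax(0, 1 - gap / width))
}

# Per-frame axis-aligned bounding boxes of confident keypoints, in image
# coordinates. Frames with < 2 confident keypoints or a degenerate box give
# NA rows.
frame_boxes <- function(seq, conf_threshold = 0.1) {
  n <- n_frames(seq)
  out <- data.frame(x_min = rep(NA_real_, n), x_max = NA_real_,
                    y_min = NA_real_, y_max = NA_real_)
  for (i in seq_len(n)) {
    sel <- seq$coords[i, , 3] > conf_threshold
    if (sum(sel) < 2L) next
    x <- seq$coords[i, sel, 1]
    y <- seq$coords[i, sel, 2]
    if (max(x) == min(x) || max(y) == min(y)) next
    out[i, ] <- c(min(x), max(x), min(y), max(y))
  }
  out
}
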