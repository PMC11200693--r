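#' Read OpenPose BODY_25 JSON output into a pose sequence
#'
#' Consumes the per-frame JSON files written by OpenPose-style estimators:
#' each file holds a `people` array whose entries carry a flat
#' `pose_keypoints_2d` vector of 75 numbers (25 joints x (x, y, confidence)).
#' Files are taken in the order given, one frame per file. The walking
#' protocol records a single walker, so a frame with more than one person is
#' an error; a frame with no detected person yields 25 confidence-0 keypoints
#' and a warning.
#'
#' @param paths Character vector of JSON file paths, in frame order.
#' @param fps Frames per second of the source video.
#' @param subject_id,direction,label,path_length_m Sequence metadata; see
#'   [pose_sequence()].
#' @return A [pose_sequence()].
#' @export
read_openpose_json <- function(paths, fps, subject_id = "unknown",
                               direction = "toward", label = "unlabeled",
                               path_length_m = 5) {
  if (length(paths) == 0L) stop("no input files")
  n <- length(paths)
  coords <- array(0, dim = c(n, N_JOINTS, 3))
  for (i in seq_len(n)) {
    rec <- jsonlite::fromJSON(paths[i], simplifyVector = FALSE)
    people <- rec$people
    if (is.null(people) || length(people) == 0L) {
      warning(sprintf("frame %d ('%s'): no person detected; emitting missing keypoints",
                      i - 1L, basename(paths[i])))
      next
    }
    if (length(people) > 1L)
      stop(sprintf("frame %d ('%s'): %d people detected; single-walker input required",
                   i - 1L, basename(paths[i]), length(people)))
    kp <- unlist(people[[1]]$pose_keypoints_2d, use.names = FALSE)
    if (length(kp) != 3L * N_JOINTS)
      stop(sprintf("frame %d ('%s'): pose_keypoints_2d has %d values, expected 75",
                   i - 1L, basename(paths[i]), length(kp)))
    coords[i, , ] <- matrix(kp, ncol = 3, byrow = TRUE)
  }
  # absent keypoints arrive as (0, 0, 0) and stay missing
  coords[, , 3][coords[, , 3] < 0] <- 0
  pose_sequence(coords, fps = fps, subject_id = subject_id,
                direction = direction, label = label,
                path_length_m = path_length_m)
}

#' Write a pose sequence as long-format CSV
#'
#' One row per frame x joint with columns `subject_id, frame_index, timestamp,
#' joint_id, x, y, confidence`. Coordinates are serialised with six decimals,
#' so a write/read round trip is lossless at that precision. `fps`,
#' `direction`, `label` and `path_length_m` are stored in `#`-prefixed header
#' comments so the file is self-describing.
#'
#' @param seq A [pose_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(seq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps=%.10g direction=%s label=%s path_length_m=%.10g",
                     seq$fps, seq$direction, seq$label, seq$path_length_m), con)
  writeLines("subject_id,frame_index,timestamp,joint_id,x,y,confidence", con)
  n <- n_frames(seq)
  if (n > 0L) {
    joint <- rep(0:(N_JOINTS - 1L), times = n)
    frame <- rep(seq$frame_index, each = N_JOINTS)
    ts <- rep(seq$timestamp, each = N_JOINTS)
    x <- as.vector(t(seq$coords[, , 1]))
    y <- as.vector(t(seq$coords[, , 2]))
    cf <- as.vector(t(seq$coords[, , 3]))
    writeLines(sprintf("%s,%d,%.6f,%d,%.6f,%.6f,%.6f",
                       seq$subject_id, frame, ts, joint, x, y, cf), con)
  }
  invisible(path)
}

#' Read a pose sequence from the long-format CSV dialect
#'
#' Inverse of [write_pose_csv()]. Malformed rows abort with the offending
#' line number. Metadata absent from the header comment falls back to the
#' function arguments.
#'
#' @param path CSV file path.
#' @param fps,subject_id,direction,label,path_length_m Fallback metadata used
#'   when the file header does not carry them.
#' @return A [pose_sequence()].
#' @export
read_pose_csv <- function(path, fps = NULL, subject_id = NULL,
                          direction = NULL, label = NULL,
                          path_length_m = NULL) {
  lines <- readLines(path)
  meta <- list()
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr)) {
    kv <- regmatches(hdr[1], gregexpr("[A-Za-z_]+=[^ ]+", hdr[1]))[[1]]
    for (pair in kv) {
      p <- strsplit(pair, "=", fixed = TRUE)[[1]]
      meta[[p[1]]] <- p[2]
    }
  }
  fps <- fps %||% suppressWarnings(as.numeric(meta$fps %||% NA))
  if (length(fps) != 1L || !is.finite(fps))
    stop("`fps` not in file header; pass it explicitly")
  direction <- direction %||% meta$direction %||% "toward"
  label <- label %||% meta$label %||% "unlabeled"
  path_length_m <- path_length_m %||% as.numeric(meta$path_length_m %||% "5")

  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0L || body[1] != "subject_id,frame_index,timestamp,joint_id,x,y,confidence")
    stop("missing or malformed CSV header row")
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  if (length(rows) == 0L) {
    return(pose_sequence(array(0, dim = c(0, N_JOINTS, 3)), fps = fps,
                         frame_index = integer(0),
                         subject_id = subject_id %||% "unknown",
                         direction = direction, label = label,
                         path_length_m = path_length_m))
  }
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 7L)
  if (length(bad))
    stop(sprintf("malformed CSV row at line %d",
                 bad[1] + length(hdr) + 1L))
  m <- matrix(unlist(parts), ncol = 7, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 2:7, drop = FALSE], 2, as.numeric))
  if (is.null(dim(num))) num <- matrix(num, ncol = 6)
  badnum <- which(rowSums(is.na(num)) > 0)
  if (length(badnum))
    stop(sprintf("malformed CSV row at line %d (non-numeric field)",
                 badnum[1] + length(hdr) + 1L))
  subject <- subject_id %||% m[1, 1]
  frame_ids <- sort(unique(as.integer(num[, 1])))
  n <- length(frame_ids)
  coords <- array(0, dim = c(n, N_JOINTS, 3))
  fi <- match(as.integer(num[, 1]), frame_ids)
  ji <- as.integer(num[, 3]) + 1L
  if (any(ji < 1L | ji > N_JOINTS)) stop("joint_id out of range 0-24")
  coords[cbind(fi, ji, 1L)] <- num[, 4]
  coords[cbind(fi, ji, 2L)] <- num[, 5]
  coords[cbind(fi, ji, 3L)] <- num[, 6]
  pose_sequence(coords, fps = fps, frame_index = frame_ids,
                subject_id = subject, direction = direction, label = label,
                path_length_m = path_length_m)
}

#' Sample frames at a fixed time interval
#'
#' Extracts the frame nearest to each grid time `t_k = k * interval_s` for
#' `k = 0, ..., ceiling(D / interval_s) - 1`, where `D` is the sequence
#' duration (last timestamp plus one frame period). The grid is anchored at
#' the first frame, so a 3 s video at 30 fps sampled every 0.3 s yields
#' exactly 10 frames. "Nearest" resolves to `round(t_k * fps)`.
#'
#' @param seq A [pose_sequence()].
#' @param interval_s Sampling interval in seconds; must be at least one frame
#'   period (`1 / fps`).
#' @return A [pose_sequence()] containing the sampled frames.
#' @export
sample_frames <- function(seq, interval_s) {
  if (n_frames(seq) == 0L) stop("cannot sample an empty sequence")
  if (interval_s <= 0) stop("`interval_s` must be > 0")
  if (interval_s < 1 / seq$fps - 1e-12)
    stop("`interval_s` is finer than the source frame period (1/fps)")
  d <- duration_s(seq)
  k <- seq_len(ceiling(d / interval_s)) - 1
  target <- round(k * interval_s * seq$fps)  # target source-frame numbers
  # nearest available frame for each target (frames may be non-contiguous)
  fi <- seq$frame_index
  if (length(fi) == 1L) return(subset_frames(seq, 1L))
  pos <- findInterval(target, fi, all.inside = TRUE)
  use_next <- (target - fi[pos]) > (fi[pmin(pos + 1L, length(fi))] - target)
  pos <- pmin(pos + as.integer(use_next), length(fi))
  pos <- unique(pos)
  subset_frames(seq, pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
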