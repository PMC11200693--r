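# features_tsr: iso-block corners, the four corner regressions and the
# TAR/BAR/velocity features.

make_frame_seq <- function(points_list, conf_list = NULL, fps = 30) {
  n <- length(points_list)
  coords <- array(0, dim = c(n, 25, 3))
  for (i in seq_len(n)) {
    pts <- points_list[[i]]
    k <- nrow(pts)
    coords[i, 1:k, 1] <- pts[, 1]
    coords[i, 1:k, 2] <- pts[, 2]
    coords[i, 1:k, 3] <- if (is.null(conf_list)) 1 else conf_list[[i]]
  }
  pose_sequence(coords, fps = fps)
}

test_that("iso-block corners follow the Cartesian flip definition", {
  pts <- rbind(c(0, 0), c(2, 1), c(1, 3))
  seq1 <- make_frame_seq(list(pts))
  conf <- rep(0, 25); conf[1:3] <- 1
  seq1$coords[1, , 3] <- conf
  ib <- extract_isoblock(seq1, image_height = 10)
  expect_equal(ib$x_lt, 0); expect_equal(ib$y_lt, 10)
  expect_equal(ib$x_rt, 2); expect_equal(ib$y_rt, 10)
  expect_equal(ib$x_lb, 0); expect_equal(ib$y_lb, 7)
  expect_equal(ib$x_rb, 2); expect_equal(ib$y_rb, 7)
})

test_that("confidence-0 keypoints are excluded from the box", {
  pts <- rbind(c(10, 10), c(20, 20), c(5000, 5000))
  seq1 <- make_frame_seq(list(pts))
  conf <- rep(0, 25); conf[1:2] <- 1  # the extreme third point is missing
  seq1$coords[1, , 3] <- conf
  ib <- extract_isoblock(seq1, image_height = 1080)
  expect_equal(ib$x_rt, 20)
  expect_equal(ib$y_lb, 1080 - 20)
})

test_that("per-frame boxes match a brute-force min/max oracle on a walk", {
  w <- sample_frames(generate_walk(walker_params(skew_deg = 3, seed = 5),
                                   "toward"), 0.3)
  ib <- extract_isoblock(w, conf_threshold = 0.1, image_height = 1080)
  for (i in seq_len(nrow(ib))) {
    vis <- w$coords[i, , 3] > 0.1
    expect_equal(ib$x_lt[i], min(w$coords[i, vis, 1]))
    expect_equal(ib$x_rt[i], max(w$coords[i, vis, 1]))
    expect_equal(ib$y_lt[i], 1080 - min(w$coords[i, vis, 2]))
    expect_equal(ib$y_lb[i], 1080 - max(w$coords[i, vis, 2]))
  }
})

test_that("frames without a valid box are dropped; > 50% dropped errors", {
  pts <- rbind(c(0, 0), c(2, 1), c(1, 3))
  seqs <- make_frame_seq(list(pts, pts, pts))
  seqs$coords[2, , 3] <- 0  # frame 2 has no confident keypoints
  expect_warning(ib <- extract_isoblock(seqs, image_height = 10), "dropped 1")
  expect_equal(nrow(ib), 2L)

  seqs$coords[3, , 3] <- 0
  expect_error(suppressWarnings(extract_isoblock(seqs, image_height = 10)),
               "more than half")
})

test_that("exact lines are recovered exactly", {
  mk_series <- function(x, y) {
    df <- data.frame(frame_index = seq_along(x) - 1,
                     timestamp = (seq_along(x) - 1) / 30,
                     x_lt = x, y_lt = y, x_rt = x, y_rt = y,
                     x_lb = x, y_lb = y, x_rb = x, y_rb = y)
    class(df) <- c("isoblock_series", "data.frame")
    df
  }
  f1 <- fit_tsr(mk_series(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(f1$lt$alpha, 0); expect_equal(f1$lt$beta, 1)
  f2 <- fit_tsr(mk_series(c(0, 1, 2), c(1, 3, 5)))
  expect_equal(f2$rb$alpha, 1); expect_equal(f2$rb$beta, 2)
  expect_equal(f2$rb$residual_sd, 0, tolerance = 1e-12)
  expect_error(fit_tsr(mk_series(c(1, 1, 1), c(0, 1, 2))), "degenerate.*lt")
})

test_that("fit_tsr matches the normal-equations oracle on noisy data", {
  set.seed(20)
  for (rep in 1:20) {
    x <- rnorm(50, sd = 10)
    y <- 2.5 - 0.7 * x + rnorm(50)
    df <- data.frame(frame_index = 0:49, timestamp = (0:49) / 30,
                     x_lt = x, y_lt = y, x_rt = x, y_rt = y,
                     x_lb = x, y_lb = y, x_rb = x, y_rb = y)
    class(df) <- c("isoblock_series", "data.frame")
    fit <- fit_tsr(df)$lt
    oracle <- ols_oracle(x, y)
    expect_equal(fit$alpha, oracle[["alpha"]], tolerance = 1e-9)
    expect_equal(fit$beta, oracle[["beta"]], tolerance = 1e-9)
  }
})

mk_fits <- function(blt, brt, blb, brb) {
  fits <- list(lt = list(corner = "lt", alpha = 0, beta = blt, residual_sd = 0, n = 10),
               rt = list(corner = "rt", alpha = 0, beta = brt, residual_sd = 0, n = 10),
               lb = list(corner = "lb", alpha = 0, beta = blb, residual_sd = 0, n = 10),
               rb = list(corner = "rb", alpha = 0, beta = brb, residual_sd = 0, n = 10))
  class(fits) <- "tsr_fits"
  fits
}

test_that("TAR and BAR implement the sign-adjusted arctangent ratio", {
  f <- compute_tar_bar(mk_fits(1, 1, 1, 1))
  expect_identical(f$tar, 1); expect_identical(f$bar, 1)

  f2 <- compute_tar_bar(mk_fits(-2, 0.5, -1, 0.25))
  expect_equal(f2$tar, atan(2) / atan(0.5), tolerance = 1e-12)
  expect_equal(f2$bar, atan(1) / atan(0.25), tolerance = 1e-12)

  # sign(0) = +1: zero numerator gives 0, not NaN
  f3 <- compute_tar_bar(mk_fits(0, 1, 0, 1))
  expect_true(f3$valid)
  expect_equal(f3$tar, 0)

  # zero denominator marks the feature invalid, no exception
  f4 <- compute_tar_bar(mk_fits(1, 0, 1, 1))
  expect_false(f4$valid)
  expect_match(f4$reason, "denominator")
})

test_that("mirror reflection maps TAR to 1/TAR and BAR to 1/BAR exactly", {
  w <- generate_walk(walker_params(skew_deg = 4, seed = 10), "away")
  f <- walk_features(w)
  fm <- walk_features(mirror_seq(w))
  expect_equal(fm$tar, 1 / f$tar, tolerance = 1e-9)
  expect_equal(fm$bar, 1 / f$bar, tolerance = 1e-9)
})

test_that("uniform isotropic rescaling leaves TAR and BAR unchanged", {
  w <- generate_walk(walker_params(skew_deg = 3, seed = 12), "toward")
  s <- sample_frames(w, 0.3)
  ib <- extract_isoblock(s)
  scaled <- ib
  for (cn in c("x_lt", "y_lt", "x_rt", "y_rt", "x_lb", "y_lb", "x_rb", "y_rb"))
    scaled[[cn]] <- 2.7 * scaled[[cn]]
  f1 <- compute_tar_bar(fit_tsr(ib))
  f2 <- compute_tar_bar(fit_tsr(scaled))
  expect_equal(f2$tar, f1$tar, tolerance = 1e-9)
  expect_equal(f2$bar, f1$bar, tolerance = 1e-9)
})

test_that("velocity is path length over traversal time", {
  seq1 <- make_seq(rep(100, 223), rep(100, 223), fps = 30)  # 7.4 s span + 1 frame
  seq1$path_length_m <- 5
  # timestamps 0 .. 222/30 = 7.4 s
  expect_equal(compute_velocity(seq1), 5 / 7.4, tolerance = 1e-12)
  seq2 <- make_seq(rep(1, 151), rep(1, 151), fps = 30)
  expect_equal(compute_velocity(seq2), 1, tolerance = 1e-12)

  w <- generate_walk(walker_params(speed_mps = 0.68, seed = 2), "toward")
  expect_equal(compute_velocity(w), 0.68, tolerance = 0.02 * 0.68)
})

test_that("group ordering on a synthetic cohort matches the calibration", {
  walks <- generate_cohort(cohort_spec(n_subjects = 9, walks_per_subject = 2,
                                       frac_left = 1 / 3, frac_right = 1 / 3,
                                       noise_sd_px = 0, dropout_rate = 0,
                                       seed = 21))
  feats <- cohort_features(walks)
  m <- tapply(feats$tar[feats$valid], feats$label[feats$valid], mean)
  expect_gt(m[["skew_left"]], 1)
  expect_lt(m[["skew_right"]], 1)
  expect_gt(m[["skew_left"]], m[["straight"]])
  expect_gt(m[["straight"]], m[["skew_right"]])
})
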