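# End-to-end orchestration: simulate (or load) walks, sample frames, build
# diagnostic DJNPs, extract TAR/BAR/velocity, run the group statistics, the
# cross-validated SVM and the pairwise ROC analyses, and write every
# artifact plus a manifest into a run directory.

#' Pipeline configuration
#'
#' @param out_dir Run directory to create/write.
#' @param input_dir Optional directory of pose CSV files (the
#'   [write_pose_csv()] dialect); when `NULL` a synthetic cohort is
#'   generated.
#' @param cohort A [cohort_spec()] used when `input_dir` is `NULL`.
#' @param interval_s Frame-sampling interval in seconds.
#' @param conf_threshold Minimum keypoint confidence.
#' @param sigma_px,downscale DJNP kernel width and grid downscale factor.
#' @param image_size Source image size `c(width, height)`.
#' @param folds,svm_C,svm_gamma SVM cross-validation settings.
#' @param seed Seed for fold assignment (the cohort has its own seed).
#' @param djnp_max Number of walks (from the start of the cohort) to export
#'   as DJNP PNGs; 0 disables image export.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL, cohort = cohort_spec(),
                            interval_s = 0.3, conf_threshold = 0.1,
                            sigma_px = 3, downscale = 4,
                            image_size = c(1920, 1080),
                            folds = 10, svm_C = 1, svm_gamma = NULL,
                            seed = 1L, djnp_max = 3) {
  if (interval_s <= 0) stop("`interval_s` must be > 0")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Deterministic given the seeds in the config: rerunning with the same
#' config produces byte-identical `features.csv`. Artifacts written to the
#' run directory: `features.csv`, `report.json` (SVM), `roc.json` (pairwise
#' cutting points), `kruskal_wallis.json`, `djnp/*.png`, `dropped.csv` and
#' `manifest.json` (config, package version, sample bookkeeping).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `features`, `report`, `roc`, `kw`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(cfg$input_dir)) {
    walks <- generate_cohort(cfg$cohort)
  } else {
    files <- sort(list.files(cfg$input_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("stage input: no CSV files in input_dir")
    walks <- lapply(files, read_pose_csv)
  }

  feats <- cohort_features(walks, interval_s = cfg$interval_s,
                           conf_threshold = cfg$conf_threshold,
                           image_height = cfg$image_size[2])
  write_features_csv(feats, file.path(cfg$out_dir, "features.csv"))

  dropped <- feats[!feats$valid, , drop = FALSE]
  utils::write.csv(dropped[, c("subject", "walk", "label", "reason")],
                   file.path(cfg$out_dir, "dropped.csv"), row.names = FALSE)
  ok <- feats[feats$valid & is.finite(feats$tar) & is.finite(feats$bar) &
                is.finite(feats$velocity_mps), , drop = FALSE]

  if (cfg$djnp_max > 0) {
    dir.create(file.path(cfg$out_dir, "djnp"), showWarnings = FALSE)
    for (i in seq_len(min(cfg$djnp_max, length(walks)))) {
      d <- build_djnp(sample_frames(walks[[i]], cfg$interval_s),
                      sigma_px = cfg$sigma_px, downscale = cfg$downscale,
                      conf_threshold = cfg$conf_threshold,
                      image_size = cfg$image_size)
      djnp_png(d, file.path(cfg$out_dir, "djnp",
                            sprintf("walk_%03d_%s.png", i, walks[[i]]$label)))
    }
  }

  kw <- lapply(c(tar = "tar", bar = "bar", velocity_mps = "velocity_mps"),
               function(col) {
    res <- kruskal_wallis(split(ok[[col]], ok$label))
    list(H = res$H, df = res$df, p_value = res$p_value)
  })
  jsonlite::write_json(kw, file.path(cfg$out_dir, "kruskal_wallis.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- train_svm_cv(ok[, c("tar", "bar", "velocity_mps")], ok$label,
                         folds = cfg$folds, seed = cfg$seed, C = cfg$svm_C,
                         gamma = cfg$svm_gamma)
  jsonlite::write_json(list(
    confusion = report$confusion,
    classes = rownames(report$confusion),
    per_class_recall = report$per_class_recall,
    per_class_precision = report$per_class_precision,
    accuracy = report$accuracy, kappa = report$kappa,
    folds = report$folds, seed = report$seed,
    fold_assignment_hash = sum(report$fold_assignment *
                                 seq_along(report$fold_assignment))),
    file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)

  roc <- list()
  for (feat in c("tar", "bar")) {
    for (grp in c("skew_left", "skew_right")) {
      a <- ok[[feat]][ok$label == "straight"]
      b <- ok[[feat]][ok$label == grp]
      if (length(a) && length(b)) {
        r <- roc_analysis(a, b)
        roc[[paste(feat, "straight_vs", grp, sep = "_")]] <-
          list(auc = r$auc, p_value = r$p_value, cp = r$cp,
               direction = r$direction)
      }
    }
  }
  jsonlite::write_json(roc, file.path(cfg$out_dir, "roc.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("skewgait")),
    n_walks = length(walks), n_features = nrow(feats),
    n_valid = nrow(ok), n_dropped = nrow(dropped),
    seed = cfg$seed,
    cohort_seed = if (is.null(cfg$input_dir)) cfg$cohort$seed else NA,
    interval_s = cfg$interval_s, conf_threshold = cfg$conf_threshold,
    sigma_px = cfg$sigma_px, downscale = cfg$downscale,
    folds = cfg$folds, svm_C = cfg$svm_C)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(features = feats, report = report, roc = roc, kw = kw,
                 manifest = manifest))
}

# Deterministic feature CSV writer (fixed 6-decimal formatting so identical
# runs are byte-identical).
write_features_csv <- function(feats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("subject,walk,direction,label,tar,bar,velocity_mps,valid,n_frames,reason", con)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  writeLines(sprintf("%s,%s,%s,%s,%s,%s,%s,%s,%s,%s",
                     feats$subject, feats$walk, feats$direction, feats$label,
                     fmt(feats$tar), fmt(feats$bar), fmt(feats$velocity_mps),
                     feats$valid, feats$n_frames, feats$reason), con)
  invisible(path)
}
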