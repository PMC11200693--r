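# Soft-margin RBF-kernel support vector classifier. No SVM library is
# assumed: the binary C-SVC dual is solved by sequential minimal
# optimisation with maximal-violating-pair working-set selection (the
# standard SMO stopping rule m(alpha) - M(alpha) < tol), and multiclass
# problems are handled one-vs-one with majority voting.

rbf_kernel <- function(x1, x2 = x1, gamma) {
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  exp(-gamma * pmax(d2, 0))
}

# Binary C-SVC via SMO. y in {-1, +1}. Returns alpha, b and the training
# rows needed for prediction.
svm_fit_binary <- function(x, y, C = 1, gamma = 1, tol = 1e-3,
                           max_iter = 50000L) {
  n <- nrow(x)
  K <- rbf_kernel(x, gamma = gamma)
  alpha <- numeric(n)
  f <- numeric(n)  # f_i = sum_j alpha_j y_j K_ij
  pos <- y > 0
  for (it in seq_len(max_iter)) {
    viol <- y - f
    i_up <- (pos & alpha < C) | (!pos & alpha > 0)
    i_low <- (pos & alpha > 0) | (!pos & alpha < C)
    m_val <- max(viol[i_up])
    m_low <- min(viol[i_low])
    if (m_val - m_low < tol) break
    i <- which(i_up)[which.max(viol[i_up])]
    j <- which(i_low)[which.min(viol[i_low])]
    quad <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (quad <= 1e-12) quad <- 1e-12
    t_star <- (viol[i] - viol[j]) / quad
    # box constraints on t: alpha_i + y_i t and alpha_j - y_j t stay in [0, C]
    lo <- if (y[i] > 0) -alpha[i] else alpha[i] - C
    hi <- if (y[i] > 0) C - alpha[i] else alpha[i]
    lo <- max(lo, if (y[j] > 0) alpha[j] - C else -alpha[j])
    hi <- min(hi, if (y[j] > 0) alpha[j] else C - alpha[j])
    t_clip <- min(max(t_star, lo), hi)
    if (abs(t_clip) < 1e-14) break
    alpha[i] <- alpha[i] + y[i] * t_clip
    alpha[j] <- alpha[j] - y[j] * t_clip
    f <- f + t_clip * (K[, i] - K[, j])
  }
  viol <- y - f
  i_up <- (pos & alpha < C) | (!pos & alpha > 0)
  i_low <- (pos & alpha > 0) | (!pos & alpha < C)
  b <- (max(viol[i_up]) + min(viol[i_low])) / 2
  sv <- alpha > 1e-12
  list(x = x[sv, , drop = FALSE], coef = (alpha * y)[sv], b = b,
       gamma = gamma)
}

svm_decision_binary <- function(fit, xnew) {
  if (length(fit$coef) == 0L) return(rep(fit$b, nrow(xnew)))
  drop(rbf_kernel(xnew, fit$x, fit$gamma) %*% fit$coef) + fit$b
}

#' Fit an RBF-kernel SVM classifier
#'
#' One-vs-one decomposition with majority voting (ties broken by the summed
#' decision values). Features should be standardised by the caller;
#' [train_svm_cv()] does this per fold.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Factor of class labels.
#' @param C Soft-margin cost.
#' @param gamma RBF kernel width; default `1 / (ncol(x) * mean(var))`, the
#'   usual "scale" heuristic.
#' @return An `svm_model` for [predict.svm_model()].
#' @export
svm_fit <- function(x, y, C = 1, gamma = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (is.null(gamma)) {
    v <- mean(apply(x, 2, stats::var))
    gamma <- if (v > 0) 1 / (ncol(x) * v) else 1
  }
  lv <- levels(y)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    yy <- ifelse(y[sel] == pr[2], 1, -1)  # second level is +1
    svm_fit_binary(x[sel, , drop = FALSE], yy, C = C, gamma = gamma)
  })
  structure(list(fits = fits, pairs = pairs, levels = lv, C = C,
                 gamma = gamma),
            class = "svm_model")
}

#' Predict classes from a fitted SVM
#'
#' @param object An [svm_fit()] model.
#' @param newdata Numeric feature matrix on the training scale.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.svm_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  lv <- object$levels
  votes <- matrix(0, nrow(x), length(lv), dimnames = list(NULL, lv))
  score <- matrix(0, nrow(x), length(lv), dimnames = list(NULL, lv))
  for (k in seq_along(object$fits)) {
    pr <- object$pairs[[k]]
    d <- svm_decision_binary(object$fits[[k]], x)
    win <- ifelse(d > 0, pr[2], pr[1])
    for (cl in pr) votes[, cl] <- votes[, cl] + (win == cl)
    score[, pr[2]] <- score[, pr[2]] + d
    score[, pr[1]] <- score[, pr[1]] - d
  }
  pick <- vapply(seq_len(nrow(x)), function(i) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1L) best <- best[which.max(score[i, best])]
    lv[best]
  }, character(1))
  factor(pick, levels = lv)
}

#' Cross-validated RBF-SVM classification report
#'
#' Stratified k-fold cross-validation: folds are assigned per class from a
#' seeded shuffle, features are standardised with training-fold statistics
#' only, and out-of-fold predictions are pooled into a single confusion
#' matrix from which recall, precision, accuracy and Cohen's kappa are
#' computed.
#'
#' @param features Numeric matrix or data.frame of features (e.g. columns
#'   tar, bar, velocity_mps). Rows with non-finite values must be dropped by
#'   the caller.
#' @param labels Class labels (coerced to factor).
#' @param folds Number of CV folds (default 10); every class must have at
#'   least `folds` members.
#' @param seed RNG seed for the fold assignment.
#' @param C,gamma SVM hyperparameters; `gamma = NULL` uses the scale
#'   heuristic on the standardised training fold.
#' @return A `classification_report`: `confusion` (truth rows x predicted
#'   columns), `per_class_recall`, `per_class_precision`, `accuracy`,
#'   `kappa`, `folds`, `seed`, `fold_assignment`.
#' @export
train_svm_cv <- function(features, labels, folds = 10, seed = 1L, C = 1,
                         gamma = NULL) {
  x <- as.matrix(features)
  if (!all(is.finite(x))) stop("features must be finite; drop invalid samples first")
  y <- droplevels(as.factor(labels))
  n <- nrow(x)
  if (length(y) != n) stop("labels length must match feature rows")
  cls_n <- table(y)
  if (any(cls_n < folds))
    stop(sprintf("class '%s' has %d samples, fewer than %d folds; use fewer folds",
                 names(cls_n)[which.min(cls_n)], min(cls_n), folds))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  fold <- integer(n)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }

  pred <- factor(rep(levels(y)[1], n), levels = levels(y))
  for (k in seq_len(folds)) {
    tr <- fold != k
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    xs_tr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    xs_te <- sweep(sweep(x[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    model <- svm_fit(xs_tr, y[tr], C = C, gamma = gamma)
    pred[!tr] <- predict(model, xs_te)
  }

  confusion <- table(truth = y, predicted = pred)
  recall <- diag(confusion) / rowSums(confusion)
  precision <- diag(confusion) / pmax(colSums(confusion), 1)
  structure(list(confusion = unclass(confusion),
                 per_class_recall = recall,
                 per_class_precision = precision,
                 accuracy = sum(diag(confusion)) / n,
                 kappa = cohens_kappa(confusion),
                 folds = folds, seed = seed, fold_assignment = fold),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: accuracy = %.3f, kappa = %.3f\n",
              x$folds, x$accuracy, x$kappa))
  print(x$confusion)
  cat("recall:    ", sprintf("%s %.3f", names(x$per_class_recall),
                             x$per_class_recall), "\n")
  cat("precision: ", sprintf("%s %.3f", names(x$per_class_precision),
                             x$per_class_precision), "\n")
  invisible(x)
}
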