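# stats_ml: Kruskal-Wallis, Cohen's kappa, ROC analysis and the
# cross-validated RBF-SVM.

test_that("Kruskal-Wallis matches the hand rank-sum oracle", {
  # ranks 1..9, R = (6, 15, 24): H = 12/(9*10) * sum(R^2/3) - 3*10 = 7.2
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res$H, 7.2, tolerance = 1e-12)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, stats::pchisq(7.2, 2, lower.tail = FALSE))
})

test_that("constant groups give H = 0 and empty groups error", {
  res <- kruskal_wallis(list(rep(5, 4), rep(5, 4), rep(5, 4)))
  expect_equal(res$H, 0)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("H agrees with stats::kruskal.test including ties (property)", {
  set.seed(31)
  for (rep in 1:20) {
    g <- list(sample(1:6, 8, TRUE), sample(1:6, 10, TRUE), sample(1:6, 7, TRUE))
    res <- kruskal_wallis(g)
    ref <- stats::kruskal.test(unlist(g), rep(1:3, lengths(g)))
    expect_equal(res$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(32)
  g <- list(rnorm(10), rnorm(12) + 0.5, rnorm(9) - 0.3)
  h0 <- kruskal_wallis(g)$H
  expect_equal(kruskal_wallis(lapply(g, exp))$H, h0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(lapply(g, function(v) 3 * v - 100))$H, h0,
               tolerance = 1e-12)
})

test_that("Cohen's kappa follows the stated formula", {
  expect_equal(cohens_kappa(diag(c(10, 10, 10))), 1)
  expect_equal(cohens_kappa(matrix(25, 2, 2)), 0)
  expect_equal(cohens_kappa(rbind(c(20, 5), c(10, 15))), 0.4, tolerance = 1e-12)
  # degenerate chance agreement
  expect_equal(cohens_kappa(matrix(c(7, 0, 0, 0), 2)), 1)
  expect_equal(cohens_kappa(matrix(c(0, 3, 0, 0), 2)), 0)
  expect_error(cohens_kappa(matrix(0, 2, 2)), "empty")
})

test_that("ROC handles separation, identity and the 0.75 pair-count case", {
  r1 <- roc_analysis(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$auc, 1)
  expect_equal(r1$cp, 3.5)
  expect_identical(r1$direction, "greater_indicates_positive")

  r2 <- roc_analysis(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$auc, 0.5)

  r3 <- roc_analysis(c(1, 3), c(2, 4))
  expect_equal(r3$auc, 0.75)

  # identical constant groups: undefined cutting point
  r4 <- roc_analysis(rep(2, 5), rep(2, 5))
  expect_equal(r4$auc, 0.5)
  expect_false(r4$cp_defined)
})

test_that("orientation flips so AUC >= 0.5 with direction recorded", {
  r <- roc_analysis(c(4, 5, 6), c(1, 2, 3))  # positives are smaller
  expect_equal(r$auc, 1)
  expect_identical(r$direction, "less_indicates_positive")
  expect_lt(r$cp, 4)
})

test_that("curve integral equals the rank AUC and the pair-count oracle", {
  set.seed(33)
  for (rep in 1:25) {
    a <- sample(1:10, sample(3:12, 1), TRUE)  # ties on purpose
    b <- sample(2:12, sample(3:12, 1), TRUE)
    r <- roc_analysis(a, b)
    expect_equal(auc_trapezoid(r$curve), r$auc, tolerance = 1e-9)
    oracle <- auc_pairs_oracle(a, b)
    expect_equal(r$auc, max(oracle, 1 - oracle), tolerance = 1e-9)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }
})

test_that("ROC p-value matches the tie-corrected Mann-Whitney approximation", {
  set.seed(34)
  a <- rnorm(20); b <- rnorm(25) + 1
  r <- roc_analysis(a, b)
  ref <- suppressWarnings(stats::wilcox.test(b, a, exact = FALSE,
                                             correct = FALSE))
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("SVM separates two well-separated clouds perfectly", {
  set.seed(40)
  x <- rbind(matrix(rnorm(100, 0), ncol = 2),
             matrix(rnorm(100, 10), ncol = 2))
  y <- rep(c("a", "b"), each = 50)
  rep_ <- train_svm_cv(x, y, folds = 10, seed = 1)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$kappa, 1)
  expect_equal(sum(rep_$confusion), 100)
})

test_that("SVM decision boundary is nonlinear (concentric rings)", {
  set.seed(41)
  th <- runif(120, 0, 2 * pi)
  r <- rep(c(1, 4), each = 60) + rnorm(120, sd = 0.15)
  x <- cbind(r * cos(th), r * sin(th))
  y <- rep(c("inner", "outer"), each = 60)
  rep_ <- train_svm_cv(x, y, folds = 5, seed = 2)
  expect_gt(rep_$accuracy, 0.95)  # a linear separator would be near 0.5
})

test_that("a class smaller than the fold count errors helpfully", {
  x <- matrix(rnorm(30), ncol = 2)
  y <- c(rep("a", 10), rep("b", 5))
  expect_error(train_svm_cv(x, y, folds = 10, seed = 1), "fewer than 10 folds")
  expect_error(train_svm_cv(cbind(c(1, NA, 3)), c("a", "b", "a"), folds = 1),
               "finite")
})

test_that("three-class SVM report pools folds into one confusion matrix", {
  f <- simulate_features(seed = 5)
  rep_ <- train_svm_cv(f[, c("tar", "bar", "velocity_mps")], f$label,
                       folds = 10, seed = 5)
  expect_equal(sum(rep_$confusion), 210)
  expect_equal(rownames(rep_$confusion), colnames(rep_$confusion))
  expect_equal(rep_$accuracy, sum(diag(rep_$confusion)) / 210)
  expect_true(all(rep_$per_class_recall >= 0 & rep_$per_class_recall <= 1))
  # deterministic given the seed
  rep2 <- train_svm_cv(f[, c("tar", "bar", "velocity_mps")], f$label,
                       folds = 10, seed = 5)
  expect_identical(rep_$confusion, rep2$confusion)
})
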