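# Statistical battery: Kruskal-Wallis across the three walking groups,
# Cohen's kappa on pooled cross-validation confusion matrices, and ROC
# analysis (Mann-Whitney AUC, Youden cutting point) for the pairwise group
# comparisons.

#' Kruskal--Wallis rank test across groups
#'
#' Tie-corrected H statistic on average ranks with a chi-squared reference
#' distribution on `G - 1` degrees of freedom.
#'
#' @param groups List of two or more numeric vectors, one per group. A named
#'   list propagates group names into the summaries.
#' @return A `kw_result`: `H`, `df`, `p_value`, and `group_summaries`
#'   (data.frame of n, mean, sd per group).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  if (n < 3L) stop("need at least 3 observations in total")
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(pooled)
  rs <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(pooled)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- if (tie_corr > 0) h / tie_corr else 0
  df <- length(groups) - 1L
  summaries <- data.frame(
    group = names(groups) %||% as.character(seq_along(groups)),
    n = as.integer(lengths(groups)),
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)))
  structure(list(H = h, df = df,
                 p_value = stats::pchisq(h, df, lower.tail = FALSE),
                 group_summaries = summaries),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
              x$H, x$df, x$p_value))
  print(x$group_summaries, row.names = FALSE)
  invisible(x)
}

#' Cohen's unweighted kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace / total` and chance agreement
#' `p_e = sum(row_i * col_i) / total^2`.
#'
#' @param confusion Square numeric matrix of counts, rows = truth,
#'   columns = predicted.
#' @return Kappa value (<= 1).
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  total <- sum(confusion)
  if (total <= 0) stop("empty confusion matrix")
  p_o <- sum(diag(confusion)) / total
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (p_e >= 1) {
    if (p_o == 1) return(1)
    stop("chance agreement is 1 but observed agreement is not; kappa undefined")
  }
  (p_o - p_e) / (1 - p_e)
}

#' ROC analysis of a single feature between two groups
#'
#' AUC via the rank (Mann--Whitney) identity with ties counted one half; the
#' orientation is chosen automatically so `auc >= 0.5`, with the chosen
#' direction recorded. The cutting point is the threshold (midpoint between
#' adjacent distinct pooled values) maximising Youden's `J = tpr - fpr`, ties
#' broken toward the threshold nearest the midpoint of the two group means.
#' The p-value tests AUC = 0.5 through the tie-corrected normal approximation
#' to the Mann--Whitney U statistic.
#'
#' @param values_a Feature values of the reference (negative) group.
#' @param values_b Feature values of the positive group.
#' @return A `roc_result`: `auc`, `p_value`, `cp`, `cp_defined`, `direction`
#'   (`"greater_indicates_positive"` or `"less_indicates_positive"`), and
#'   `curve` (data.frame of fpr, tpr, threshold from (0,0) to (1,1)).
#' @export
roc_analysis <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na == 0L || nb == 0L) stop("both groups must be nonempty")
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  auc_greater <- (sum(r[(na + 1):(na + nb)]) - nb * (nb + 1) / 2) / (na * nb)
  direction <- if (auc_greater >= 0.5) "greater_indicates_positive"
               else "less_indicates_positive"
  auc <- max(auc_greater, 1 - auc_greater)

  # tie-corrected normal approximation for U
  nn <- na + nb
  u <- auc_greater * na * nb
  ties <- table(pooled)
  var_u <- na * nb / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  p_value <- if (var_u <= 0) 1 else
    2 * stats::pnorm(-abs((u - na * nb / 2) / sqrt(var_u)))

  uq <- sort(unique(pooled))
  if (length(uq) == 1L) {
    curve <- data.frame(fpr = c(0, 1), tpr = c(0, 1),
                        threshold = c(Inf, -Inf))
    res <- list(auc = 0.5, p_value = 1, cp = NA_real_, cp_defined = FALSE,
                direction = direction, curve = curve)
    class(res) <- "roc_result"
    return(res)
  }
  mids <- (uq[-1] + uq[-length(uq)]) / 2
  pos_gt <- direction == "greater_indicates_positive"
  stat <- function(thr) {
    pred_pos_a <- if (pos_gt) values_a > thr else values_a < thr
    pred_pos_b <- if (pos_gt) values_b > thr else values_b < thr
    c(fpr = mean(pred_pos_a), tpr = mean(pred_pos_b))
  }
  m <- t(vapply(mids, stat, numeric(2)))
  # order thresholds so the curve runs (0,0) -> (1,1)
  ord <- if (pos_gt) order(mids, decreasing = TRUE) else order(mids)
  curve <- data.frame(fpr = c(0, m[ord, "fpr"], 1),
                      tpr = c(0, m[ord, "tpr"], 1),
                      threshold = c(if (pos_gt) Inf else -Inf, mids[ord],
                                    if (pos_gt) -Inf else Inf))
  j <- m[, "tpr"] - m[, "fpr"]
  best <- which(j == max(j))
  if (length(best) > 1L) {
    centre <- (mean(values_a) + mean(values_b)) / 2
    best <- best[which.min(abs(mids[best] - centre))]
  }
  res <- list(auc = auc, p_value = p_value, cp = mids[best],
              cp_defined = TRUE, direction = direction, curve = curve)
  class(res) <- "roc_result"
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (p = %.4g), CP = %s, %s\n",
              x$auc, x$p_value,
              ifelse(x$cp_defined, sprintf("%.4f", x$cp), "undefined"),
              x$direction))
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' Integrates an ordered (fpr, tpr) curve; used as the independent check
#' against the rank-based AUC.
#'
#' @param curve data.frame with `fpr` and `tpr` ordered from (0,0) to (1,1).
#' @return Area under the curve.
#' @export
auc_trapezoid <- function(curve) {
  f <- curve$fpr; t <- curve$tpr
  sum(diff(f) * (t[-1] + t[-length(t)]) / 2)
}
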