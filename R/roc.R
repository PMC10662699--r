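#' Area under the ROC curve by pairwise concordance
#'
#' Mann-Whitney estimate of the AUC: the probability that a randomly
#' chosen positive sample scores higher than a randomly chosen negative
#' one, with ties counting one half. Computed via midranks.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (see [select_per_method()] conventions).
#' @param positive Positive class for character/factor labels.
#' @return The AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels, positive = NULL) {
  y <- as_binary_label(labels, positive)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) stopf("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ROC curve points (FPR, TPR) over all score thresholds.
roc_points <- function(scores, labels, positive = NULL) {
  y <- as_binary_label(labels, positive)
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord] == 1L) / sum(y == 1L))
  fpr <- c(0, cumsum(y[ord] == 0L) / sum(y == 0L))
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  data.frame(fpr = fpr[c(TRUE, keep)], tpr = tpr[c(TRUE, keep)])
}

# Placement values (structural components) of one score vector:
# V10[i] = mean_j psi(x_i, y_j) over negatives, V01[j] over positives.
delong_components <- function(scores, y) {
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi), theta = mean(psi))
}

#' DeLong comparison of two correlated ROC curves
#'
#' Nonparametric test of the AUC difference between two classifiers
#' scored on the same samples, using the fast structural-components
#' (placement value) covariance estimate and a two-sided normal
#' approximation.
#'
#' @param scores_a,scores_b Score vectors of the two classifiers on the
#'   same samples.
#' @param labels Binary labels.
#' @param positive Positive class for character/factor labels.
#' @return List with `auc_a`, `auc_b`, `z`, `p`. Identical score vectors
#'   give `z = 0, p = 1`; a degenerate variance otherwise yields `NaN`
#'   with a warning.
#' @export
delong_compare <- function(scores_a, scores_b, labels, positive = NULL) {
  if (length(scores_a) != length(scores_b)) {
    stopf("score vectors must cover the same samples")
  }
  y <- as_binary_label(labels, positive)
  if (!all(c(0L, 1L) %in% y)) stopf("both classes must be present")
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  m <- sum(y == 1L); n <- sum(y == 0L)
  s10 <- cov(cbind(ca$v10, cb$v10))
  s01 <- cov(cbind(ca$v01, cb$v01))
  # Note v01 stores 1 - colMeans(psi) = placement of negatives; its
  # covariance structure is identical to that of colMeans(psi).
  v <- (s10[1, 1] - 2 * s10[1, 2] + s10[2, 2]) / m +
       (s01[1, 1] - 2 * s01[1, 2] + s01[2, 2]) / n
  d <- ca$theta - cb$theta
  if (d == 0) {
    z <- 0; p <- 1
  } else if (v <= 0 || !is.finite(v)) {
    warning("degenerate DeLong variance; p reported as NaN", call. = FALSE)
    z <- NaN; p <- NaN
  } else {
    z <- d / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = ca$theta, auc_b = cb$theta, z = z, p = p)
}
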