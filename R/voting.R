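#' Hard (majority) vote over per-model class predictions
#'
#' Returns the majority class among the model predictions together with
#' the agreement count. Ties are broken toward the positive class:
#' sensitivity is the clinically critical property, so an undecided
#' ensemble flags the case class rather than missing it.
#'
#' @param votes Character vector of per-model predicted class labels
#'   (at least two models).
#' @param positive Positive class label (default `"PCa"`).
#' @return List with `class` and `agreement` (votes for the winning
#'   class).
#' @export
#' @examples
#' hard_vote(c("PCa", "PCa", "PCa", "PCa", "BPH"))  # PCa, agreement 4
hard_vote <- function(votes, positive = "PCa") {
  if (length(votes) < 2L) stopf("need at least two model votes")
  counts <- table(votes)
  top <- max(counts)
  winners <- names(counts)[counts == top]
  cls <- if (positive %in% winners) positive else winners[1L]
  list(class = cls, agreement = as.integer(counts[cls]))
}

#' Soft (performance-weighted) vote
#'
#' Each model's class prediction is weighted by its F1 score on the test
#' set; the class with the larger summed weight wins, ties going to the
#' positive class.
#'
#' @param votes Character vector of per-model predicted class labels.
#' @param weights Non-negative per-model weights (typically test-set F1),
#'   not all zero.
#' @param positive Positive class label (default `"PCa"`).
#' @return List with `class` and `weight` (summed weight of the winning
#'   class).
#' @export
soft_vote <- function(votes, weights, positive = "PCa") {
  if (length(votes) != length(weights)) stopf("one weight per vote required")
  if (any(weights < 0)) stopf("weights must be >= 0")
  if (sum(weights) == 0) stopf("all-zero weights")
  sums <- tapply(weights, votes, sum)
  top <- max(sums)
  winners <- names(sums)[sums == top]
  cls <- if (positive %in% winners) positive else winners[1L]
  list(class = cls, weight = unname(sums[cls]))
}

#' Ensemble voting on grey-zone samples
#'
#' Scores each grey-zone sample with every fitted model, thresholds the
#' probabilities into class predictions, and applies both the hard
#' (majority) and soft (F1-weighted) voting strategies.
#'
#' @param report An `evaluation_report` from [train_and_score()] whose
#'   `scorers` were fitted on the model-building set.
#' @param greyzone Data frame of grey-zone samples (feature columns
#'   required; a label column, if present, is used to count correct
#'   assignments).
#' @param label_col,negative Label column and negative class label used
#'   for the probability-to-class threshold and the correctness count.
#' @return Data frame with one row per grey-zone sample: per-model
#'   predictions, `hard`, `hard_agreement`, `soft`, and `correct_hard` /
#'   `correct_soft` when the true label is available.
#' @export
vote_greyzone <- function(report, greyzone, label_col = "diagnosis",
                          negative = "BPH") {
  stopifnot(inherits(report, "evaluation_report"))
  x <- greyzone[, report$features, drop = FALSE]
  models <- names(report$scorers)
  pred <- vapply(models, function(m) {
    ifelse(report$scorers[[m]](x) >= report$cutoff, report$positive, negative)
  }, character(nrow(x)))
  pred <- matrix(pred, nrow = nrow(x),
                 dimnames = list(NULL, models))
  f1 <- report$metrics[report$metrics$metric == "f1", ]
  weights <- setNames(f1$estimate, f1$model)[models]
  out <- data.frame(sample_id = greyzone$sample_id, pred,
                    stringsAsFactors = FALSE, check.names = FALSE)
  hv <- apply(pred, 1, hard_vote, positive = report$positive)
  sv <- apply(pred, 1, soft_vote, weights = weights,
              positive = report$positive)
  out$hard <- vapply(hv, `[[`, character(1), "class")
  out$hard_agreement <- vapply(hv, `[[`, integer(1), "agreement")
  out$soft <- vapply(sv, `[[`, character(1), "class")
  if (label_col %in% names(greyzone)) {
    out$truth <- greyzone[[label_col]]
    out$correct_hard <- out$hard == out$truth
    out$correct_soft <- out$soft == out$truth
  }
  out
}
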