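#' Aggressiveness sub-analysis (AG vs NAG within the cancer group)
#'
#' Re-parameterized run of the classification pipeline restricted to the
#' cancer samples: Gleason 3+3 tumors form the non-aggressive (NAG)
#' class and anything higher the aggressive (AG) class. Feature
#' consensus is recomputed on this subset (unless `features` is given),
#' the samples are split 70/30 stratified by class, and the model panel
#' -- four classifiers, the degenerate support-vector machine of the
#' main comparison is not carried over -- is trained and scored with AG
#' as the positive class.
#'
#' @param qmat Quantification matrix from [assemble_matrix()] (must
#'   contain `aggressiveness` and the candidate variable columns).
#' @param features Optional fixed feature set; default recomputes the
#'   consensus on the cancer subset.
#' @param candidate_vars Candidate variable columns for the consensus
#'   (default: all panel peptides present plus the clinical variables).
#' @param train_frac Training fraction, default 0.70.
#' @param seed Integer seed.
#' @param models Model names, default the four-model panel.
#' @param min_votes,cap Consensus parameters (defaults 4 and 20).
#' @param boot Bootstrap resamples for CIs.
#' @return List with `report` (an `evaluation_report`), `features`,
#'   `selection` (the grid, when recomputed), and the split.
#' @export
run_aggressiveness <- function(qmat, features = NULL, candidate_vars = NULL,
                               train_frac = 0.7, seed = 1,
                               models = c("random_forest", "logistic", "knn",
                                          "decision_tree"),
                               min_votes = 4, cap = 20, boot = 2000) {
  pca <- qmat[!is.na(qmat$aggressiveness), , drop = FALSE]
  if (nrow(pca) == 0L) stopf("no samples with Gleason-based AG/NAG labels")
  candidate_vars <- candidate_vars %||% setdiff(
    names(pca)[vapply(pca, is.numeric, logical(1))],
    c("n_runs_used"))
  seeds <- derive_seeds(seed, 3L)
  selection <- NULL
  if (is.null(features)) {
    selection <- select_features(pca[, candidate_vars, drop = FALSE],
                                 pca$aggressiveness == "AG",
                                 cap = cap, seed = seeds[1])
    features <- consensus(selection, min_votes = min_votes)$variable
    if (!length(features)) stopf("consensus selected no variables")
  }
  split <- with_seed(seeds[2],
    stratified_split(pca$sample_id, pca$aggressiveness, train_frac))
  train <- pca[pca$sample_id %in% split$train, ]
  test <- pca[pca$sample_id %in% split$test, ]
  report <- train_and_score(train, test, features,
                            label_col = "aggressiveness", positive = "AG",
                            models = models, seed = seeds[3], boot = boot)
  list(report = report, features = features, selection = selection,
       split = split)
}
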