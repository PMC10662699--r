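CLASSIFIER_MODELS <- c("random_forest", "logistic", "knn", "svm", "decision_tree")

# Fit one classifier on a feature data frame and return a closure that
# scores new data with the positive-class probability.
fit_scorer <- function(model, x_train, y_train, seed, knn_k = 5) {
  y <- factor(y_train, levels = c(0, 1))
  switch(model,
    random_forest = {
      rf <- with_seed(seed, randomForest::randomForest(x_train, y, ntree = 500))
      out <- function(newx) unname(predict(rf, newx, type = "prob")[, "1"])
      attr(out, "importance") <- sort(rf$importance[, "MeanDecreaseGini"],
                                      decreasing = TRUE)
      out
    },
    logistic = {
      dat <- cbind(x_train, .y = as.integer(y_train))
      fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
      function(newx) unname(suppressWarnings(predict(fit, newx,
                                                     type = "response")))
    },
    knn = {
      centers <- colMeans(x_train)
      scales <- apply(x_train, 2, sd)
      scales[scales == 0] <- 1
      tr <- scale(x_train, centers, scales)
      function(newx) {
        te <- scale(newx, centers, scales)
        pred <- with_seed(seed, class::knn(tr, te, y, k = knn_k, prob = TRUE))
        pr <- attr(pred, "prob")
        ifelse(pred == "1", pr, 1 - pr)
      }
    },
    svm = {
      fit <- with_seed(seed, e1071::svm(x_train, y, kernel = "radial",
                                        probability = TRUE))
      function(newx) {
        pred <- predict(fit, newx, probability = TRUE)
        unname(attr(pred, "probabilities")[, "1"])
      }
    },
    decision_tree = {
      dat <- cbind(x_train, .y = y)
      fit <- with_seed(seed, rpart::rpart(
        .y ~ ., data = dat, method = "class",
        control = rpart::rpart.control(cp = 0, xval = 0)))
      function(newx) unname(predict(fit, newx, type = "prob")[, "1"])
    },
    stopf("unknown model '%s'", model))
}

# Confusion-matrix metrics at a probability cutoff.
classification_metrics <- function(scores, y, cutoff = 0.5) {
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  c(auc = auc_score(scores, y),
    f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
    accuracy = (tp + tn) / length(y),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

confusion_matrix <- function(scores, y, cutoff = 0.5) {
  pred <- factor(as.integer(scores >= cutoff), levels = c(0, 1))
  table(predicted = pred, truth = factor(y, levels = c(0, 1)))
}

# Stratified bootstrap CIs over the test set: resample within each class
# and recompute the metrics.
bootstrap_cis <- function(scores, y, cutoff, boot, seed, level = 0.95) {
  idx_pos <- which(y == 1L); idx_neg <- which(y == 0L)
  with_seed(seed, {
    stats <- replicate(boot, {
      idx <- c(sample(idx_pos, replace = TRUE), sample(idx_neg, replace = TRUE))
      classification_metrics(scores[idx], y[idx], cutoff)
    })
    a <- (1 - level) / 2
    t(apply(stats, 1, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  })
}

#' Train the classifier panel and score a test set
#'
#' Fits each model on the training samples only, scores the test
#' samples with positive-class probabilities, and reports AUC, F1,
#' accuracy, specificity and sensitivity (positive class = the case
#' group) with stratified-bootstrap 95% confidence intervals.
#'
#' @param train,test Data frames containing the feature columns and the
#'   label column.
#' @param features Character vector of feature column names.
#' @param label_col Label column name (default `"diagnosis"`).
#' @param positive Positive class label (default `"PCa"`).
#' @param models Model names among `"random_forest"`, `"logistic"`,
#'   `"knn"`, `"svm"`, `"decision_tree"` (default all five).
#' @param seed Integer seed (model fitting and bootstrap).
#' @param boot Bootstrap resamples for the CIs (default 2000; `0` skips
#'   the CIs).
#' @param cutoff Probability cutoff for the class metrics (default 0.5).
#' @return List of class `evaluation_report`: `metrics` (long data frame
#'   `model`, `metric`, `estimate`, `lower`, `upper`), `scores` (test
#'   samples x models), `confusion` (per model), `roc` (per model FPR/TPR
#'   points), `importance` (random-forest mean decrease in Gini, when
#'   fitted), `scorers` (the fitted scoring closures), and bookkeeping
#'   (`n_train`, `n_test`, `features`, `positive`, `cutoff`).
#' @export
train_and_score <- function(train, test, features, label_col = "diagnosis",
                            positive = "PCa", models = CLASSIFIER_MODELS,
                            seed = 1, boot = 2000, cutoff = 0.5) {
  models <- match.arg(models, CLASSIFIER_MODELS, several.ok = TRUE)
  miss <- setdiff(features, names(train))
  if (length(miss)) stopf("features absent from the data: %s",
                          paste(miss, collapse = ", "))
  if (length(unique(train[[label_col]])) < 2L) {
    stopf("training labels are single-class")
  }
  y_train <- as_binary_label(train[[label_col]], positive)
  y_test <- as_binary_label0(test[[label_col]], positive)
  x_train <- train[, features, drop = FALSE]
  x_test <- test[, features, drop = FALSE]
  seeds <- derive_seeds(seed, length(models) + 1L)

  scorers <- list(); scores <- list(); metrics <- list()
  confusion <- list(); roc <- list(); importance <- NULL
  for (k in seq_along(models)) {
    m <- models[k]
    scorers[[m]] <- fit_scorer(m, x_train, y_train, seeds[k])
    s <- scorers[[m]](x_test)
    scores[[m]] <- s
    est <- classification_metrics(s, y_test, cutoff)
    ci <- if (boot > 0) {
      bootstrap_cis(s, y_test, cutoff, boot, seeds[length(models) + 1L])
    } else {
      matrix(NA_real_, length(est), 2, dimnames = list(names(est), NULL))
    }
    metrics[[m]] <- data.frame(model = m, metric = names(est),
                               estimate = unname(est),
                               lower = unname(ci[, 1]), upper = unname(ci[, 2]),
                               stringsAsFactors = FALSE)
    confusion[[m]] <- confusion_matrix(s, y_test, cutoff)
    roc[[m]] <- roc_points(s, y_test)
    if (m == "random_forest") {
      importance <- attr(scorers[[m]], "importance")
    }
  }
  structure(list(metrics = do.call(rbind, metrics),
                 scores = do.call(cbind, scores), confusion = confusion,
                 roc = roc, importance = importance, scorers = scorers,
                 n_train = nrow(train), n_test = nrow(test),
                 features = features, positive = positive, cutoff = cutoff),
            class = "evaluation_report")
}

# Tolerant label coercion for test sets that may be single-class.
as_binary_label0 <- function(y, positive) {
  if (is.character(y) || is.factor(y)) as.integer(as.character(y) == positive)
  else as_binary_label(y)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d train / %d test samples, %d features\n",
              x$n_train, x$n_test, length(x$features)))
  wide <- reshape_metrics(x$metrics)
  print(wide, digits = 3, row.names = FALSE)
  invisible(x)
}

reshape_metrics <- function(metrics) {
  models <- unique(metrics$model)
  out <- data.frame(model = models, stringsAsFactors = FALSE)
  for (met in unique(metrics$metric)) {
    sub <- metrics[metrics$metric == met, ]
    out[[met]] <- sub$estimate[match(models, sub$model)]
  }
  out
}
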