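SELECTION_METHODS <- c("pearson", "chi2", "rfe", "logistic_l1", "random_forest")

# Coerce the label to 0/1 with 1 = positive class.
as_binary_label <- function(y, positive = NULL) {
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) {
    u <- sort(unique(y))
    if (!all(u %in% c(0, 1))) stopf("numeric labels must be 0/1")
    return(as.integer(y))
  }
  y <- as.character(y)
  u <- sort(unique(y))
  if (length(u) != 2L) stopf("labels must be binary (got %d classes)", length(u))
  positive <- positive %||% u[2L]
  as.integer(y == positive)
}

scale01 <- function(x) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# Chi-square score of a non-negative feature against a binary class:
# observed per-class feature totals against totals expected from class
# frequencies (the convention of count-style univariate selection).
chi2_score <- function(x01, y) {
  obs <- c(sum(x01[y == 0]), sum(x01[y == 1]))
  expd <- sum(x01) * c(mean(y == 0), mean(y == 1))
  if (any(expd == 0)) return(0)
  sum((obs - expd)^2 / expd)
}

balanced_weights <- function(y) {
  w <- length(y) / (2 * table(y))
  as.numeric(w[as.character(y)])
}

# Recursive feature elimination with an L2-logistic base estimator
# (balanced class weights, standardized features): iteratively drop the
# feature with the smallest absolute coefficient until `cap` remain.
# Returns the full elimination ranking (1 = retained longest).
rfe_rank <- function(x, y, cap) {
  xs <- scale(x)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  surviving <- colnames(x)
  rank_out <- setNames(rep(NA_real_, ncol(x)), colnames(x))
  next_rank <- ncol(x)
  w <- balanced_weights(y)
  while (length(surviving) > max(cap, 1L)) {
    fit <- glmnet::glmnet(xs[, surviving, drop = FALSE], y,
                          family = "binomial", alpha = 0, lambda = 1e-4,
                          weights = w, standardize = FALSE)
    cf <- abs(as.numeric(coef(fit))[-1])
    worst <- surviving[which.min(cf)]
    rank_out[worst] <- next_rank
    next_rank <- next_rank - 1L
    surviving <- setdiff(surviving, worst)
  }
  if (length(surviving) > 1L) {
    fit <- glmnet::glmnet(xs[, surviving, drop = FALSE], y,
                          family = "binomial", alpha = 0, lambda = 1e-4,
                          weights = w, standardize = FALSE)
    cf <- abs(as.numeric(coef(fit))[-1])
    rank_out[surviving] <- rank(-cf, ties.method = "first")
  } else {
    rank_out[surviving] <- 1
  }
  rank_out
}

#' Select features with a single method
#'
#' Runs one of the five feature selectors on a numeric feature matrix
#' against a binary label and returns the capped boolean selection. The
#' score-based selectors (absolute Pearson correlation, chi-square on
#' min-max scaled features, random-forest impurity importance, recursive
#' feature elimination with an L2-logistic base estimator) take the top
#' `cap` by score; the L1-penalized logistic selector takes the nonzero
#' coefficients at a regularization chosen by 5-fold cross-validation
#' (the parsimonious one-standard-error rule), truncated to `cap`.
#' Constant features are excluded from the ranking with a warning. Ties
#' in any ranking are broken by variable name for determinism.
#'
#' @param x Numeric data frame or matrix of candidate variables.
#' @param y Binary labels (logical, 0/1, or two-level factor/character;
#'   for character labels the alphabetically later level is positive
#'   unless `positive` is given).
#' @param method One of `"pearson"`, `"chi2"`, `"rfe"`, `"logistic_l1"`,
#'   `"random_forest"`.
#' @param cap Maximum number of selected variables (default 20).
#' @param seed Integer seed for the stochastic selectors.
#' @param positive Positive class label for character/factor `y`.
#' @return Named logical vector of selections with the method's ranking
#'   (1 = best, `Inf` = unranked) as attribute `"rank"`.
#' @export
select_per_method <- function(x, y, method = SELECTION_METHODS, cap = 20,
                              seed = 1, positive = NULL) {
  method <- match.arg(method)
  x <- as.data.frame(x)
  if (any(!vapply(x, is.numeric, logical(1)))) {
    stopf("all candidate variables must be numeric")
  }
  if (anyNA(x)) stopf("missing values in the feature matrix (impute upstream)")
  y <- as_binary_label(y, positive)
  if (length(unique(y)) < 2L) stopf("labels are single-class")
  assert_positive_count(cap, "cap")
  vars <- names(x)
  xm <- as.matrix(x)

  constant <- apply(xm, 2, function(v) var(v) == 0)
  if (any(constant)) {
    warning(sprintf("constant features excluded from %s ranking: %s", method,
                    paste(vars[constant], collapse = ", ")), call. = FALSE)
  }
  usable <- vars[!constant]
  ranks <- setNames(rep(Inf, length(vars)), vars)
  if (cap == 0L || length(usable) == 0L) {
    sel <- setNames(rep(FALSE, length(vars)), vars)
    attr(sel, "rank") <- ranks
    return(sel)
  }
  xu <- xm[, usable, drop = FALSE]

  score_rank <- function(score) {
    # higher score = better; deterministic name tie-break
    ord <- order(-score, usable)
    setNames(match(usable, usable[ord]), usable)
  }
  ranks[usable] <- with_seed(seed, switch(method,
    pearson = score_rank(abs(as.numeric(cor(xu, y)))),
    chi2 = {
      x01 <- apply(xu, 2, scale01)
      score_rank(apply(x01, 2, chi2_score, y = y))
    },
    rfe = if (length(usable) == 1L) setNames(1, usable) else rfe_rank(xu, y, cap),
    logistic_l1 = {
      if (length(usable) == 1L) setNames(1, usable) else {
        foldid <- sample(rep_len(1:5, length(y)))
        cvfit <- glmnet::cv.glmnet(xu, y, family = "binomial", alpha = 1,
                                   foldid = foldid)
        cf <- as.numeric(coef(cvfit, s = "lambda.1se"))[-1]
        std_cf <- abs(cf) * apply(xu, 2, sd)
        r <- setNames(rep(Inf, length(usable)), usable)
        nz <- std_cf > 0
        if (any(nz)) {
          ord <- order(-std_cf[nz], usable[nz])
          r[usable[nz][ord]] <- seq_len(sum(nz))
        }
        r
      }
    },
    random_forest = {
      rf <- randomForest::randomForest(xu, as.factor(y), ntree = 500)
      score_rank(as.numeric(rf$importance[, "MeanDecreaseGini"]))
    }
  ))
  sel <- ranks <= cap
  attr(sel, "rank") <- ranks
  sel
}

#' Run all feature selectors and tabulate the votes
#'
#' Applies every method in `methods` (each capped at `cap` variables) and
#' assembles the variables-by-methods boolean selection grid with a vote
#' total per variable.
#'
#' @inheritParams select_per_method
#' @param methods Selector names, default all five.
#' @return Data frame with columns `variable`, one logical column per
#'   method, and `total`; the per-method rank matrix is attached as
#'   attribute `"ranks"`.
#' @export
select_features <- function(x, y, methods = SELECTION_METHODS, cap = 20,
                            seed = 1, positive = NULL) {
  x <- as.data.frame(x)
  seeds <- derive_seeds(seed, length(methods))
  sels <- mapply(function(m, s) {
    select_per_method(x, y, m, cap = cap, seed = s, positive = positive)
  }, methods, seeds, SIMPLIFY = FALSE)
  grid <- data.frame(variable = names(x), stringsAsFactors = FALSE)
  for (m in methods) grid[[m]] <- unname(sels[[m]][grid$variable])
  grid$total <- rowSums(grid[, methods, drop = FALSE])
  attr(grid, "ranks") <- vapply(sels, function(s) attr(s, "rank")[grid$variable],
                                numeric(nrow(grid)))
  grid
}

#' Consensus over the selection grid
#'
#' Keeps the variables selected by at least `min_votes` methods, ordered
#' by vote total (descending) and then mean rank across methods
#' (ascending; unranked counts as worst). On a grid without rank
#' information the original row order breaks ties (printed grids list
#' variables in decreasing significance).
#'
#' @param selection Selection grid from [select_features()] (or a
#'   compatible data frame with a `variable` column, method columns and
#'   optionally `total`).
#' @param min_votes Minimum number of agreeing methods, default 4.
#' @return Data frame `variable`, `votes`, ordered as described.
#' @export
#' @examples
#' consensus(glyco_fixture("selection_grid"))  # the 11 printed variables
consensus <- function(selection, min_votes = 4) {
  methods <- intersect(SELECTION_METHODS, names(selection))
  total <- selection$total %||% rowSums(selection[, methods, drop = FALSE])
  ranks <- attr(selection, "ranks")
  mean_rank <- if (!is.null(ranks)) {
    rowMeans(apply(ranks, 2, function(r) ifelse(is.finite(r), r, nrow(selection) + 1)))
  } else {
    seq_len(nrow(selection))  # printed order = decreasing significance
  }
  keep <- which(total >= min_votes)
  keep <- keep[order(-total[keep], mean_rank[keep], selection$variable[keep])]
  data.frame(variable = selection$variable[keep], votes = total[keep],
             stringsAsFactors = FALSE)
}

#' Write a selection grid as TSV
#'
#' @param selection Grid from [select_features()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_selection_grid <- function(selection, path) {
  write.table(selection, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
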