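test_that("cohort splitting reproduces the study arithmetic", {
  cohort <- generate_cohort(cohort_config(), seed = 1)
  sp <- split_cohort(cohort, seed = 1)
  expect_equal(length(sp$greyzone), 20)
  expect_equal(length(sp$train), 100)
  expect_equal(length(sp$test), 43)
  expect_equal(length(c(sp$greyzone, sp$train, sp$test)), 163)
  expect_false(any(duplicated(c(sp$greyzone, sp$train, sp$test))))
  # grey zone drawn only from tPSA in [4, 10]
  tpsa <- cohort$tPSA[match(sp$greyzone, cohort$sample_id)]
  expect_true(all(tpsa >= 4 & tpsa <= 10))
  # determinism
  expect_identical(sp, split_cohort(cohort, seed = 1))
  expect_false(identical(sp$greyzone, split_cohort(cohort, seed = 2)$greyzone))
  # stratified 70/30 on the cancer-only subset: 79 -> 55 / 24
  pca <- cohort[cohort$diagnosis == "PCa", ]
  ag_split <- glycoPRM:::with_seed(3,
    glycoPRM:::stratified_split(pca$sample_id, pca$aggressiveness, 0.7))
  expect_equal(length(ag_split$train), 55)
  expect_equal(length(ag_split$test), 24)
  # too few eligible grey-zone samples is an error
  low <- cohort; low$tPSA <- 1
  expect_error(split_cohort(low, seed = 1), "eligible")
})

test_that("AUC equals the brute-force pairwise concordance on small inputs", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(n), 1))  # coarse scores force ties
    expect_equal(auc_score(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("DeLong variance matches the exhaustive structural-components oracle", {
  set.seed(62)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    y <- c(0, 1, sample(c(0, 1), n - 2, replace = TRUE))
    sa <- rnorm(n); sb <- rnorm(n)
    ours <- delong_compare(sa, sb, y)
    v <- oracle_delong_var(sa, sb, y)
    expect_equal(ours$auc_a, oracle_auc(sa, y), tolerance = 1e-12)
    if (is.finite(ours$z) && ours$z != 0) {
      expect_equal((ours$auc_a - ours$auc_b) / ours$z, sqrt(v),
                   tolerance = 1e-10)
    }
  }
})

test_that("DeLong handles the degenerate and perfect-separation cases", {
  y <- rep(c(0, 1), 10)
  s <- seq_len(20)
  same <- delong_compare(s, s, y)
  expect_equal(same$z, 0); expect_equal(same$p, 1)
  y2 <- rep(c(0, 1), each = 10)
  # perfect separation has zero placement variance: flagged, not silent
  expect_warning(res <- delong_compare(1:20, 20:1, y2), "degenerate")
  expect_equal(res$auc_a, 1); expect_equal(res$auc_b, 0)
  expect_true(is.nan(res$p))
})

test_that("DeLong p is invariant under strictly monotone score transforms", {
  set.seed(63)
  y <- sample(c(0, 1), 40, replace = TRUE, prob = c(0.5, 0.5))
  y[1:2] <- c(0, 1)
  sa <- rnorm(40); sb <- rnorm(40) + 0.4 * y
  base <- delong_compare(sa, sb, y)
  warped <- delong_compare(exp(sa), atan(sb) * 3 + 7, y)
  expect_equal(base$p, warped$p, tolerance = 1e-12)
  expect_equal(base$z, warped$z, tolerance = 1e-12)
})

test_that("agreement with an established DeLong implementation", {
  skip_if_not_installed("pROC")
  set.seed(64)
  y <- rep(c(0, 1), each = 20)
  sa <- rnorm(40) + y; sb <- rnorm(40) + 0.5 * y
  ours <- delong_compare(sa, sb, y)
  ref <- pROC::roc.test(pROC::roc(y, sa, quiet = TRUE, direction = "<"),
                        pROC::roc(y, sb, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})

test_that("hard voting equals the majority oracle on every 5-model pattern", {
  for (code in 0:31) {
    votes <- ifelse(intToBits(code)[1:5] == 1, "PCa", "BPH")
    hv <- hard_vote(votes)
    expect_equal(hv$class, oracle_majority(votes, "PCa"))
    expect_equal(hv$agreement, sum(votes == hv$class))
    # equal weights reduce soft voting to hard voting
    sv <- soft_vote(votes, rep(1, 5))
    expect_equal(sv$class, hv$class)
  }
  # 2k-model tie goes to the positive class
  expect_equal(hard_vote(c("PCa", "BPH"))$class, "PCa")
  expect_error(hard_vote("PCa"), "at least two")
})

test_that("soft voting weighs predictions by model performance", {
  votes <- c("PCa", "BPH", "BPH", "BPH", "BPH")
  expect_equal(soft_vote(votes, c(0.9, 0.1, 0.1, 0.1, 0.1))$class, "PCa")
  # a zero-weight model never changes the outcome
  for (code in 0:15) {
    v4 <- ifelse(intToBits(code)[1:4] == 1, "PCa", "BPH")
    w <- c(0.7, 0.3, 0.4, 0.2)
    with_extra <- soft_vote(c(v4, "PCa"), c(w, 0))
    expect_equal(with_extra$class, soft_vote(v4, w)$class)
  }
  expect_error(soft_vote(votes, rep(0, 5)), "all-zero")
  expect_error(soft_vote(votes, c(1, 1)), "one weight per vote")
})

test_that("metrics derive exactly from the confusion matrix", {
  set.seed(65)
  y <- sample(c(0, 1), 60, replace = TRUE)
  y[1:2] <- c(0, 1)
  s <- runif(60)
  m <- glycoPRM:::classification_metrics(s, y, cutoff = 0.5)
  pred <- as.integer(s >= 0.5)
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  fp <- sum(pred & !y); fn <- sum(!pred & y)
  expect_equal(unname(m["accuracy"]), (tp + tn) / 60)
  expect_equal(unname(m["sensitivity"]), tp / (tp + fn))
  expect_equal(unname(m["specificity"]), tn / (tn + fp))
  expect_equal(unname(m["f1"]), 2 * tp / (2 * tp + fp + fn))
  cm <- glycoPRM:::confusion_matrix(s, y, 0.5)
  expect_equal(sum(cm), 60)
})

test_that("a perfectly separable test set gives perfect scores", {
  glycoPRM:::with_seed(66, {
    n <- 80
    y <- rep(c("BPH", "PCa"), each = n / 2)
    dat <- data.frame(f1 = ifelse(y == "PCa", 5, 0) + rnorm(n, sd = 0.1),
                      f2 = rnorm(n), diagnosis = y,
                      stringsAsFactors = FALSE)
    idx <- c(1:30, 41:70)
    rep <- train_and_score(dat[idx, ], dat[-idx, ], c("f1", "f2"),
                           models = "random_forest", seed = 5, boot = 50)
    auc <- rep$metrics[rep$metrics$metric == "auc", ]
    sens <- rep$metrics[rep$metrics$metric == "sensitivity", ]
    expect_equal(auc$estimate, 1)
    expect_equal(sens$estimate, 1)
    expect_true(all(rep$metrics$lower <= rep$metrics$estimate + 1e-12 &
                      rep$metrics$estimate <= rep$metrics$upper + 1e-12))
  })
})

test_that("shuffled labels give chance-level test AUC", {
  glycoPRM:::with_seed(67, {
    n <- 143
    dat <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(dat) <- sprintf("f%d", 1:6)
    aucs <- vapply(1:10, function(s) {
      dat$diagnosis <- sample(rep(c("BPH", "PCa"), length.out = n))
      sp <- glycoPRM:::stratified_split(seq_len(n), dat$diagnosis, 0.7)
      rep <- train_and_score(dat[sp$train, ], dat[sp$test, ],
                             sprintf("f%d", 1:6), models = "random_forest",
                             seed = s, boot = 0)
      rep$metrics$estimate[rep$metrics$metric == "auc"]
    }, numeric(1))
    expect_gt(median(aucs), 0.35)
    expect_lt(median(aucs), 0.65)
  })
})

test_that("single-class training labels are rejected", {
  dat <- data.frame(f1 = rnorm(10), diagnosis = "PCa",
                    stringsAsFactors = FALSE)
  expect_error(train_and_score(dat, dat, "f1", seed = 1), "single-class")
})

test_that("greyzone voting assembles per-model predictions and both votes", {
  glycoPRM:::with_seed(68, {
    n <- 100
    y <- rep(c("BPH", "PCa"), each = n / 2)
    dat <- data.frame(sample_id = sprintf("G%03d", 1:n),
                      f1 = ifelse(y == "PCa", 2, 0) + rnorm(n),
                      f2 = rnorm(n), diagnosis = y, stringsAsFactors = FALSE)
    idx <- c(1:40, 51:90)
    rep <- train_and_score(dat[idx, ], dat[-idx, ], c("f1", "f2"),
                           models = c("random_forest", "logistic", "knn"),
                           seed = 6, boot = 50)
    votes <- vote_greyzone(rep, dat[-idx, ])
    expect_equal(nrow(votes), 20)
    expect_true(all(votes$hard %in% c("PCa", "BPH")))
    expect_true(all(votes$hard_agreement >= 2))
    expect_gt(mean(votes$correct_hard), 0.5)
  })
})

test_that("the aggressiveness sub-analysis runs the four-model panel", {
  cohort <- generate_cohort(cohort_config(), seed = 71)
  runs <- generate_prm_runs(cohort, signal_config(), seed = 72)
  qmat <- assemble_matrix(qc_filter(runs)$retained, cohort)
  res <- run_aggressiveness(qmat, seed = 73, boot = 0)
  expect_equal(res$report$n_train, 55)
  expect_equal(res$report$n_test, 24)
  expect_setequal(unique(res$report$metrics$model),
                  c("random_forest", "logistic", "knn", "decision_tree"))
  expect_true(length(res$features) >= 1)
  # planted moderate aggressiveness effects are detectable but modest
  auc <- res$report$metrics$estimate[
    res$report$metrics$model == "random_forest" &
      res$report$metrics$metric == "auc"]
  expect_gt(auc, 0.4)
})
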