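#' Default end-to-end pipeline configuration
#'
#' All tunable thresholds of the pipeline in one nested list, with the
#' study values as defaults: candidate-filter thresholds, the SRD and
#' 2-SD run-QC rules, the 20-variable cap and 4-of-5 vote consensus, the
#' 20-sample grey-zone holdout with tPSA in \[4, 10\] ng/mL, and the 70%
#' training fraction.
#'
#' @param ... Named overrides merged into the defaults (e.g.
#'   `qc = list(srd_max = 0.4)`).
#' @return Nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cohort = cohort_config(),
    signal = signal_config(),
    qc = list(srd_max = 0.50, sd_mult = 2),
    selection = list(cap = 20, min_votes = 4),
    split = list(holdout_greyzone = 20, train_frac = 0.7,
                 greyzone_range = c(4, 10)),
    eval = list(models = CLASSIFIER_MODELS, boot = 2000, cutoff = 0.5,
                positive = "PCa"),
    aggressiveness = list(run = TRUE, boot = 2000)
  )
  modifyList(cfg, list(...))
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate -> run QC -> normalize/assemble -> consensus
#' feature selection -> train/evaluate -> grey-zone voting ->
#' aggressiveness sub-analysis as one reproducible run, and returns a
#' manifest sufficient to reproduce it: seeds, configuration, per-stage
#' counts, every QC exclusion with its reason, the chosen features,
#' per-model metrics, the voting outcome, and (when `out_dir` is given)
#' the checksums of all written files.
#'
#' Feature selection runs on the full model-building set (grey-zone
#' samples excluded), then models are trained on the training split and
#' scored on the test split; for voting, models are refit on all
#' model-building samples.
#'
#' @param config Configuration from [pipeline_config()].
#' @param seed Integer master seed; every stage derives its own seed
#'   from it.
#' @param out_dir Optional output directory; stage tables, a ROC figure
#'   and a JSON manifest are written there.
#' @return The manifest (list of class `pipeline_manifest`), with the
#'   intermediate objects attached in `$objects`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         out_dir = NULL) {
  seeds <- derive_seeds(seed, 8L)

  samples <- generate_cohort(config$cohort, seed = seeds[1])
  runs <- generate_prm_runs(samples, config$signal, seed = seeds[2])
  qc <- qc_filter(runs, srd_max = config$qc$srd_max,
                  sd_mult = config$qc$sd_mult)
  qmat <- assemble_matrix(qc$retained, samples, config$signal$panel)

  split <- split_cohort(qmat, holdout_greyzone = config$split$holdout_greyzone,
                        train_frac = config$split$train_frac,
                        seed = seeds[3],
                        greyzone_range = config$split$greyzone_range)
  build <- qmat[qmat$sample_id %in% c(split$train, split$test), ]
  greyzone <- qmat[qmat$sample_id %in% split$greyzone, ]

  candidate_vars <- c(config$signal$panel$sequence,
                      c("age", "prostate_dimension", "proPSA", "tPSA",
                        "fPSA", "ftPSA"))
  candidate_vars <- intersect(candidate_vars, names(qmat))
  selection <- select_features(build[, candidate_vars, drop = FALSE],
                               build$diagnosis == config$eval$positive,
                               cap = config$selection$cap, seed = seeds[4])
  features <- consensus(selection, min_votes = config$selection$min_votes)$variable
  if (!length(features)) stopf("consensus selected no variables")

  train <- build[build$sample_id %in% split$train, ]
  test <- build[build$sample_id %in% split$test, ]
  report <- train_and_score(train, test, features,
                            positive = config$eval$positive,
                            models = config$eval$models, seed = seeds[5],
                            boot = config$eval$boot,
                            cutoff = config$eval$cutoff)

  # Univariate baseline: ROC on raw tPSA over the same test samples.
  tpsa_auc <- auc_score(test$tPSA, test$diagnosis,
                        positive = config$eval$positive)
  delong <- if ("random_forest" %in% config$eval$models) {
    delong_compare(report$scores[, "random_forest"], test$tPSA,
                   test$diagnosis, positive = config$eval$positive)
  }

  # Voting: refit on the full model-building set, vote the grey zone.
  vote_report <- train_and_score(build, test, features,
                                 positive = config$eval$positive,
                                 models = config$eval$models, seed = seeds[6],
                                 boot = 0, cutoff = config$eval$cutoff)
  vote_report$metrics <- report$metrics  # F1 weights from the held-out test
  votes <- vote_greyzone(vote_report, greyzone)

  ag <- if (isTRUE(config$aggressiveness$run)) {
    run_aggressiveness(build, seed = seeds[7],
                       cap = config$selection$cap,
                       min_votes = config$selection$min_votes,
                       boot = config$aggressiveness$boot)
  }

  manifest <- structure(list(
    seed = seed, stage_seeds = seeds, config = config,
    counts = list(n_samples = nrow(samples),
                  runs_generated = qc$n_runs_in,
                  runs_retained = qc$n_runs_retained,
                  n_build = nrow(build), n_train = nrow(train),
                  n_test = nrow(test), n_greyzone = nrow(greyzone)),
    qc_exclusions = qc$dropped,
    features = features,
    metrics = report$metrics,
    univariate = list(tpsa_auc = tpsa_auc, delong = delong),
    voting = list(
      hard_correct = sum(votes$correct_hard %||% NA),
      soft_correct = sum(votes$correct_soft %||% NA),
      n = nrow(votes)),
    aggressiveness = if (!is.null(ag)) list(
      features = ag$features,
      metrics = ag$report$metrics,
      n_train = ag$report$n_train, n_test = ag$report$n_test)
  ), class = "pipeline_manifest")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_simulation(runs, samples, out_dir)
    write.csv(qmat, file.path(out_dir, "quant_matrix.csv"), row.names = FALSE)
    write_qc_report(qc, file.path(out_dir, "qc_report.tsv"))
    write_selection_grid(selection, file.path(out_dir, "selection_grid.tsv"))
    write.csv(report$metrics, file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
    write.csv(votes, file.path(out_dir, "greyzone_votes.csv"),
              row.names = FALSE)
    plot_roc_png(report, tpsa_auc, test, config$eval$positive,
                 file.path(out_dir, "roc.png"))
    files <- list.files(out_dir, full.names = TRUE)
    manifest$checksums <- setNames(as.character(tools::md5sum(files)),
                                   basename(files))
    jsonlite::write_json(
      manifest[setdiff(names(manifest), "config")],
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  manifest$objects <- list(samples = samples, qc = qc, qmat = qmat,
                           split = split, selection = selection,
                           report = report, votes = votes,
                           aggressiveness = ag)
  manifest
}

plot_roc_png <- function(report, tpsa_auc, test, positive, path) {
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  plot(c(0, 1), c(0, 1), type = "n", xlab = "False positive rate",
       ylab = "True positive rate", main = "ROC, test set")
  abline(0, 1, lty = 3, col = "grey")
  cols <- seq_along(report$roc) + 1
  for (k in seq_along(report$roc)) {
    lines(report$roc[[k]]$fpr, report$roc[[k]]$tpr, col = cols[k], lwd = 2)
  }
  tp <- roc_points(test$tPSA, test$diagnosis, positive = positive)
  lines(tp$fpr, tp$tpr, col = 1, lwd = 2, lty = 2)
  legend("bottomright", lwd = 2, col = c(cols, 1),
         lty = c(rep(1, length(report$roc)), 2),
         legend = c(names(report$roc),
                    sprintf("tPSA only (AUC %.2f)", tpsa_auc)))
  invisible(path)
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d): %d samples, %d/%d runs retained\n",
              x$seed, x$counts$n_samples, x$counts$runs_retained,
              x$counts$runs_generated))
  cat("Consensus features:", paste(x$features, collapse = ", "), "\n")
  auc <- x$metrics[x$metrics$metric == "auc", ]
  cat(sprintf("Test AUC: %s | tPSA-only AUC %.3f\n",
              paste(sprintf("%s %.3f", auc$model, auc$estimate),
                    collapse = ", "),
              x$univariate$tpsa_auc))
  cat(sprintf("Grey-zone voting: hard %s/%d, soft %s/%d correct\n",
              x$voting$hard_correct, x$voting$n,
              x$voting$soft_correct, x$voting$n))
  invisible(x)
}
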