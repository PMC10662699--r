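test_that("cohort generation honours the configured design", {
  cohort <- generate_cohort(cohort_config(), seed = 1)
  expect_equal(nrow(cohort), 163)
  expect_equal(sum(cohort$diagnosis == "PCa"), 79)
  expect_equal(sum(cohort$aggressiveness == "AG", na.rm = TRUE), 53)
  expect_equal(sum(cohort$gleason == "3+3", na.rm = TRUE), 26)
  expect_true(all(is.na(cohort$gleason[cohort$diagnosis == "BPH"])))

  degenerate <- generate_cohort(cohort_config(n_pca = 0, n_bph = 5, n_nag = 0),
                                seed = 1)
  expect_equal(nrow(degenerate), 5)
  expect_true(all(degenerate$diagnosis == "BPH"))

  expect_error(cohort_config(n_pca = -1), "non-negative")
  expect_error(cohort_config(n_nag = 80), "n_ag")
  bad <- default_clinical_params <- glycoPRM:::default_clinical_params()
  bad$PCa$proPSA <- c(median = 500, q1 = 900, q3 = 300)
  expect_error(cohort_config(clinical_params = bad), "ordered")
})

test_that("clinical medians converge to the configured values", {
  big <- generate_cohort(cohort_config(n_pca = 10000, n_bph = 10000,
                                       n_nag = 3300, ag_propsa_fc = 1),
                         seed = 7)
  pca <- big[big$diagnosis == "PCa", ]
  bph <- big[big$diagnosis == "BPH", ]
  expect_lt(abs(median(pca$proPSA) - 553.9) / 553.9, 0.05)
  expect_lt(abs(median(bph$proPSA) - 257.7) / 257.7, 0.05)
  expect_lt(abs(median(pca$tPSA) - 8.05) / 8.05, 0.05)
  # a lognormal matches the median and the IQR spread (quartile ratio);
  # asymmetric bounds are not separately matchable by construction
  iqr_ratio <- quantile(pca$tPSA, 0.75) / quantile(pca$tPSA, 0.25)
  expect_lt(abs(iqr_ratio - 15.85 / 5.66) / (15.85 / 5.66), 0.08)
})

test_that("ftPSA stays consistent with fPSA and tPSA up to the noise", {
  cohort <- generate_cohort(cohort_config(), seed = 3)
  implied <- 100 * cohort$fPSA / cohort$tPSA
  log_dev <- log(cohort$ftPSA / implied)
  expect_lt(max(abs(log_dev)), 5 * 0.1)  # bounded by the noise scale
  expect_lt(abs(sd(log_dev) - 0.1), 0.03)
})

test_that("identical seed and config reproduce the dataset byte for byte", {
  cfg <- small_cohort_config()
  c1 <- generate_cohort(cfg, seed = 5)
  c2 <- generate_cohort(cfg, seed = 5)
  expect_identical(c1, c2)
  r1 <- generate_prm_runs(c1, signal_config(), seed = 9)
  r2 <- generate_prm_runs(c2, signal_config(), seed = 9)
  expect_identical(r1, r2)
  r3 <- generate_prm_runs(c1, signal_config(), seed = 10)
  expect_false(identical(r1$area, r3$area))
})

test_that("the duplicate design yields two runs per sample", {
  cohort <- generate_cohort(small_cohort_config(), seed = 2)
  runs <- generate_prm_runs(cohort,
                            signal_config(frac_discordant_runs = 0,
                                          frac_low_recovery_runs = 0),
                            seed = 2)
  per_sample <- table(unique(runs[, c("sample_id", "replicate_idx")])$sample_id)
  expect_true(all(per_sample == 2))
  single <- generate_prm_runs(cohort, signal_config(duplicate = FALSE), seed = 2)
  expect_true(all(single$replicate_idx == 1))
})

test_that("noiseless replicates have zero SRD", {
  cohort <- generate_cohort(small_cohort_config(), seed = 4)
  runs <- generate_prm_runs(cohort, noise_free_signal(), seed = 4)
  qc <- qc_filter(runs)
  expect_true(all(abs(qc$pairs$srd) < 1e-12))
})

test_that("injected discordant pairs violate the SRD rule by construction", {
  cohort <- generate_cohort(cohort_config(n_pca = 50, n_bph = 50, n_nag = 17),
                            seed = 6)
  sig <- signal_config(frac_discordant_runs = 0.1, frac_low_recovery_runs = 0)
  runs <- generate_prm_runs(cohort, sig, seed = 6)
  truth <- attr(runs, "truth")
  expect_equal(length(truth$discordant_samples), 10)
  qc <- qc_filter(runs)
  planted <- qc$pairs$sample_id %in% truth$discordant_samples
  expect_true(all(abs(qc$pairs$srd[planted]) > 0.5))
})

test_that("scaling one run's enrichment factor scales light and reference areas only", {
  cohort <- generate_cohort(small_cohort_config(5, 5, 2), seed = 8)
  sig <- signal_config(frac_discordant_runs = 0, frac_low_recovery_runs = 0)
  E <- matrix(1, 10, 2)
  base <- generate_prm_runs(cohort, sig, seed = 8, enrichment_factors = E)
  k <- 3.7
  E2 <- E; E2[4, 2] <- k
  scaled <- generate_prm_runs(cohort, sig, seed = 8, enrichment_factors = E2)
  hit <- base$sample_id == cohort$sample_id[4] & base$replicate_idx == 2
  ratio <- scaled$area / base$area
  expect_equal(ratio[hit & base$channel %in% c("light", "reference")],
               rep(k, sum(hit & base$channel != "heavy")), tolerance = 1e-12)
  expect_equal(ratio[hit & base$channel == "heavy"],
               rep(1, sum(hit & base$channel == "heavy")), tolerance = 1e-12)
  expect_equal(ratio[!hit], rep(1, sum(!hit)), tolerance = 1e-12)
})

test_that("discovery-table generation plants exactly the significant rows", {
  tab <- generate_discovery_table(50, 7, seed = 13)
  res <- filter_candidates(tab)
  expect_setequal(res$retained$sequence, tab$sequence[tab$is_significant])
  expect_equal(nrow(res$retained), 7)

  none <- generate_discovery_table(20, 0, seed = 13)
  expect_equal(nrow(filter_candidates(none)$retained), 0)
  all3 <- generate_discovery_table(3, 3, seed = 13)
  expect_equal(nrow(filter_candidates(all3)$retained), 3)
  expect_error(generate_discovery_table(5, 7), "<=")
  expect_error(generate_discovery_table(5, 2, fc_range = c(2, 1)), "lo <= hi")
})

test_that("null generator settings give chance-level discrimination", {
  # no planted proteomic or clinical differences: held-out AUC ~ 0.5
  params <- glycoPRM:::default_clinical_params()
  params$PCa <- params$BPH
  cfg <- cohort_config(n_pca = 100, n_bph = 100, n_nag = 33,
                       clinical_params = params, ag_propsa_fc = 1)
  sig <- signal_config(fold_changes = setNames(
    rep(1, 31), glyco_fixture("final_panel")$sequence),
    ag_fold_changes = setNames(rep(1, 31), glyco_fixture("final_panel")$sequence))
  aucs <- vapply(1:5, function(s) {
    cohort <- generate_cohort(cfg, seed = s)
    runs <- generate_prm_runs(cohort, sig, seed = s + 100)
    qmat <- assemble_matrix(qc_filter(runs)$retained, cohort)
    ids <- qmat$sample_id
    sp <- glycoPRM:::with_seed(s + 200,
      glycoPRM:::stratified_split(ids, qmat$diagnosis, 0.7))
    feats <- c(glyco_fixture("final_panel")$sequence, "tPSA", "proPSA")
    rep <- train_and_score(qmat[ids %in% sp$train, ], qmat[ids %in% sp$test, ],
                           feats, models = "random_forest", seed = s, boot = 0)
    rep$metrics$estimate[rep$metrics$metric == "auc"]
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("simulation writers produce the three sidecar files", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(small_cohort_config(4, 4, 1), seed = 3)
  runs <- generate_prm_runs(cohort, signal_config(), seed = 3)
  files <- write_simulation(runs, cohort, dir)
  expect_true(all(file.exists(files)))
  back <- read_prm_runs(files["runs"])
  expect_equal(nrow(back), nrow(runs))
  expect_equal(back$area, runs$area, tolerance = 1e-12)
})
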