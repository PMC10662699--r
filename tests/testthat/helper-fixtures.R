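# In-code fixture builders for the run-level QC tests.

# Build a minimal long-format run table from per-run reference sums. Each
# run gets one reference row carrying the full sum and one light row so
# downstream code sees a complete record.
make_qc_runs <- function(sample_id, replicate_idx, C) {
  rbind(
    data.frame(sample_id = sample_id, replicate_idx = replicate_idx,
               peptide_id = "REF01", channel = "reference", area = C,
               stringsAsFactors = FALSE),
    data.frame(sample_id = sample_id, replicate_idx = replicate_idx,
               peptide_id = "PEPTIDEA", channel = "light", area = 1,
               stringsAsFactors = FALSE))
}

# Noise-free signal configuration: every stochastic term switched off so
# the assembled matrix must equal baseline x fold-change exactly.
noise_free_signal <- function(...) {
  signal_config(enrichment_cv = 0, heavy_spike_cv = 0, measurement_cv = 0,
                biological_cv = 0, reference_biological_cv = 0,
                frac_discordant_runs = 0, frac_low_recovery_runs = 0, ...)
}

# Small cohort for fast end-to-end tests.
small_cohort_config <- function(n_pca = 20, n_bph = 20, n_nag = 7) {
  cohort_config(n_pca = n_pca, n_bph = n_bph, n_nag = n_nag)
}
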