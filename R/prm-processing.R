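#' Scaled relative difference between technical replicates
#'
#' Replicate-concordance statistic computed on the reference-glycopeptide
#' sums of a duplicate pair: `(c1 - c2) / (mean(c1, c2) * sqrt(2))`. A
#' value of +/- 0.5 corresponds to roughly a twofold difference in
#' glycopeptide recovery between the replicates. Antisymmetric under
#' swapping the replicates.
#'
#' @param c1,c2 Reference-glycopeptide XIC sums of replicate 1 and 2
#'   (must be positive). Vectorized.
#' @return The SRD value(s).
#' @export
#' @examples
#' compute_srd(3, 1)  # 2 / (2 * sqrt(2)) ~ 0.707
compute_srd <- function(c1, c2) {
  if (any(!is.finite(c1) | c1 <= 0) || any(!is.finite(c2) | c2 <= 0)) {
    stopf("reference sums must be positive")
  }
  (c1 - c2) / (((c1 + c2) / 2) * sqrt(2))
}

# Per-run reference-glycopeptide sums, one row per (sample, replicate).
run_reference_sums <- function(runs) {
  ref <- runs[runs$channel == "reference", , drop = FALSE]
  if (nrow(ref) == 0L) stopf("no reference-channel rows in the run table")
  cs <- aggregate(area ~ sample_id + replicate_idx, data = ref, FUN = sum)
  names(cs)[names(cs) == "area"] <- "C"
  if (any(cs$C <= 0)) stopf("non-positive reference sum encountered")
  cs[order(cs$sample_id, cs$replicate_idx), , drop = FALSE]
}

#' Replicate-concordance and low-recovery quality control
#'
#' Applies the two run-level exclusion rules of the verification phase to
#' a long-format run table. For each duplicate pair the scaled relative
#' difference of the reference-glycopeptide sums is computed; when
#' `|SRD| > srd_max` the replicate with the lower glycopeptide recovery
#' is discarded. Additionally, any run whose reference sum falls more
#' than `sd_mult` standard deviations below the dataset mean (both
#' computed over all runs before any exclusion) is discarded as an
#' enrichment failure. The surviving partner of a discordant pair is
#' exempt from the low-recovery rule so that a sample never loses both
#' replicates to the combined rules; each dropped run carries exactly one
#' reason.
#'
#' @param runs Long-format run table (`sample_id`, `replicate_idx`,
#'   `peptide_id`, `channel`, `area`).
#' @param srd_max Concordance threshold, default 0.50.
#' @param sd_mult Low-recovery multiplier, default 2.
#' @return A list of class `qc_report`: `retained` (the filtered run
#'   table), `pairs` (per-pair SRD values), `dropped` (run, reference sum
#'   and reason, one of `discordant_pair_lower_recovery`,
#'   `low_recovery_2sd`), `c_mean`, `c_sd`, and run counts.
#' @export
qc_filter <- function(runs, srd_max = 0.50, sd_mult = 2) {
  cs <- run_reference_sums(runs)
  n_runs_per_sample <- table(cs$sample_id)
  if (any(n_runs_per_sample > 2L)) {
    stopf("samples with more than two runs: %s",
          paste(names(n_runs_per_sample)[n_runs_per_sample > 2L], collapse = ", "))
  }
  c_mean <- mean(cs$C)
  c_sd <- if (nrow(cs) > 1L) sd(cs$C) else 0
  low_bound <- c_mean - sd_mult * c_sd

  dup_samples <- names(n_runs_per_sample)[n_runs_per_sample == 2L]
  pairs <- NULL
  drop <- character(0)       # keys "sample|replicate"
  reason <- character(0)
  protected <- character(0)  # surviving partners of discordant pairs
  key <- function(s, r) paste(s, r, sep = "|")
  if (length(dup_samples)) {
    c1 <- cs$C[match(key(dup_samples, 1L), key(cs$sample_id, cs$replicate_idx))]
    c2 <- cs$C[match(key(dup_samples, 2L), key(cs$sample_id, cs$replicate_idx))]
    srd <- compute_srd(c1, c2)
    pairs <- data.frame(sample_id = dup_samples, c1 = c1, c2 = c2, srd = srd,
                        stringsAsFactors = FALSE)
    disc <- abs(srd) > srd_max
    if (any(disc)) {
      lower_rep <- ifelse(c1[disc] < c2[disc], 1L, 2L)
      drop <- c(drop, key(dup_samples[disc], lower_rep))
      reason <- c(reason, rep("discordant_pair_lower_recovery", sum(disc)))
      protected <- key(dup_samples[disc], 3L - lower_rep)
    }
  }
  all_keys <- key(cs$sample_id, cs$replicate_idx)
  low <- cs$C < low_bound & !(all_keys %in% drop) & !(all_keys %in% protected)
  drop <- c(drop, all_keys[low])
  reason <- c(reason, rep("low_recovery_2sd", sum(low)))

  dropped <- data.frame(
    sample_id = sub("\\|.*$", "", drop),
    replicate_idx = as.integer(sub("^.*\\|", "", drop)),
    C = cs$C[match(drop, all_keys)],
    reason = reason, stringsAsFactors = FALSE)
  keep_rows <- !(key(runs$sample_id, runs$replicate_idx) %in% drop)
  retained <- runs[keep_rows, , drop = FALSE]
  rownames(retained) <- NULL

  structure(list(retained = retained, pairs = pairs, dropped = dropped,
                 c_mean = c_mean, c_sd = c_sd,
                 n_runs_in = nrow(cs), n_runs_retained = nrow(cs) - nrow(dropped)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("PRM run QC: %d runs in, %d retained (%d dropped)\n",
              x$n_runs_in, x$n_runs_retained, nrow(x$dropped)))
  if (nrow(x$dropped)) print(table(x$dropped$reason))
  invisible(x)
}

#' Internal-standard correction of a light-peptide area
#'
#' Multiplies a light (endogenous) area by the correction factor
#' `f = heavy_mean / heavy`, the ratio of the peptide's mean heavy
#' (internal standard) area across the sample set to its heavy area in
#' this run. A global per-run instrument response factor scales light and
#' heavy alike, so it cancels.
#'
#' @param light Light-peptide XIC area(s).
#' @param heavy Heavy-peptide XIC area(s) in the same run; zero or
#'   missing values yield `NA` (flagged missing, never divided).
#' @param heavy_mean Mean heavy area of the peptide over the sample set
#'   (> 0).
#' @return Corrected light area(s).
#' @export
is_correct <- function(light, heavy, heavy_mean) {
  if (any(!is.finite(heavy_mean) | heavy_mean <= 0)) {
    stopf("`heavy_mean` must be positive")
  }
  out <- (heavy_mean / heavy) * light
  out[!is.finite(heavy) | heavy <= 0] <- NA_real_
  out
}

#' Enrichment-efficiency normalization
#'
#' Divides a peptide area by the run's relative glycopeptide recovery
#' `c_run / c_a`, where `c_run` is the run's reference-glycopeptide sum
#' and `c_a` the average reference sum over the retained run set.
#'
#' @param area Peptide area(s).
#' @param c_run Reference sum of the run (> 0).
#' @param c_a Dataset average reference sum (> 0).
#' @return Normalized area(s).
#' @export
enrichment_normalize <- function(area, c_run, c_a) {
  if (any(!is.finite(c_run) | c_run <= 0) || any(!is.finite(c_a) | c_a <= 0)) {
    stopf("reference sums must be positive")
  }
  area / (c_run / c_a)
}

#' Assemble the sample-by-feature quantification matrix
#'
#' Turns QC-passed runs into one row per sample: per peptide, the light
#' area is internal-standard corrected (IS-mode peptides only), divided
#' by the run's relative enrichment recovery, and averaged over the
#' available replicates; clinical variables are joined by sample id.
#' The heavy means and the average reference sum are computed over the
#' retained runs (excluded runs are defective by definition). A peptide
#' missing from every run of a sample is imputed as half the cohort
#' minimum for that peptide and flagged in `attr(matrix, "imputed")`.
#'
#' @param runs Retained long-format run table (after [qc_filter()]).
#' @param samples Clinical table with `sample_id` and covariate columns;
#'   every sample present in `runs` must appear here.
#' @param panel Panel data frame (`sequence`, `quant_mode`), default the
#'   packaged final panel.
#' @param c_a Normalization constant: the average reference sum defining
#'   the unit of the normalized areas. Defaults to the mean over the
#'   retained runs; it is a pure scale choice, so fixing it externally
#'   (e.g. to compare datasets) rescales every value alike.
#' @return Data frame with one row per sample: `sample_id`, one column
#'   per panel peptide (normalized area), the clinical columns, and
#'   `n_runs_used`.
#' @export
assemble_matrix <- function(runs, samples, panel = glyco_fixture("final_panel"),
                            c_a = NULL) {
  cs <- run_reference_sums(runs)
  missing_clin <- setdiff(unique(runs$sample_id), samples$sample_id)
  if (length(missing_clin)) {
    stopf("samples missing from the clinical table: %s",
          paste(missing_clin, collapse = ", "))
  }
  c_a <- c_a %||% mean(cs$C)
  key <- function(s, r) paste(s, r, sep = "|")
  run_key <- key(cs$sample_id, cs$replicate_idx)
  c_of <- setNames(cs$C, run_key)

  light <- runs[runs$channel == "light" & runs$peptide_id %in% panel$sequence, ]
  heavy <- runs[runs$channel == "heavy" & runs$peptide_id %in% panel$sequence, ]
  heavy_means <- tapply(heavy$area[heavy$area > 0],
                        heavy$peptide_id[heavy$area > 0], mean)

  is_mode <- setNames(panel$quant_mode == "is", panel$sequence)
  lk <- key(light$sample_id, light$replicate_idx)
  hx <- setNames(heavy$area, paste(key(heavy$sample_id, heavy$replicate_idx),
                                   heavy$peptide_id))
  corrected <- light$area
  for (p in panel$sequence[is_mode[panel$sequence]]) {
    idx <- which(light$peptide_id == p)
    hm <- heavy_means[[p]]
    if (is.null(hm) || !is.finite(hm)) {
      stopf("no heavy areas found for IS-mode peptide %s", p)
    }
    corrected[idx] <- is_correct(light$area[idx],
                                 unname(hx[paste(lk[idx], p)]), hm)
  }
  normalized <- enrichment_normalize(corrected, unname(c_of[lk]), c_a)

  sample_ids <- sort(unique(runs$sample_id))
  peptides <- panel$sequence
  mat <- matrix(NA_real_, length(sample_ids), length(peptides),
                dimnames = list(sample_ids, peptides))
  agg <- tapply(normalized, list(light$sample_id, light$peptide_id),
                function(v) mean(v, na.rm = TRUE))
  mat[rownames(agg), colnames(agg)] <- agg
  mat[is.nan(mat)] <- NA_real_

  imputed <- NULL
  for (j in seq_along(peptides)) {
    nas <- is.na(mat[, j])
    if (any(nas)) {
      floor_val <- if (all(nas)) 0 else 0.5 * min(mat[!nas, j])
      mat[nas, j] <- floor_val
      imputed <- rbind(imputed, data.frame(sample_id = sample_ids[nas],
                                           peptide_id = peptides[j],
                                           value = floor_val))
    }
  }

  n_runs_used <- as.integer(table(cs$sample_id)[sample_ids])
  out <- data.frame(sample_id = sample_ids, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  clin <- samples[match(sample_ids, samples$sample_id),
                  setdiff(names(samples), "sample_id"), drop = FALSE]
  out <- cbind(out, clin)
  out$n_runs_used <- n_runs_used
  rownames(out) <- NULL
  attr(out, "imputed") <- imputed
  out
}

#' Read a long-format PRM run table
#'
#' @param path TSV with columns `sample_id`, `replicate_idx`,
#'   `peptide_id`, `channel`, `area`.
#' @return The run table as a data frame.
#' @export
read_prm_runs <- function(path) {
  runs <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate_idx", "peptide_id", "channel", "area")
  miss <- setdiff(need, names(runs))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  runs
}

#' Write a QC report to disk
#'
#' @param report A `qc_report` from [qc_filter()].
#' @param path Output TSV path listing every dropped run with its reason.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  write.table(report$dropped, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
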