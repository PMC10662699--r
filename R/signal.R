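# Default planted case/control fold-changes: the discovery fold-changes of
# the two TMT experiments mapped onto the final verification panel.
# Panel peptides that entered via the qualitative deep-fractionation
# experiment have no printed effect and default to 1.0. The NCAM1
# substitute peptide inherits the fold-change measured for the protein's
# original discovery peptide.
default_fold_changes <- function() {
  panel <- glyco_fixture("final_panel")
  fc <- setNames(rep(1, nrow(panel)), panel$sequence)
  disc <- rbind(glyco_fixture("tmta")[, c("sequence", "fold_change")],
                glyco_fixture("tmtb")[, c("sequence", "fold_change")])
  disc <- disc[!duplicated(disc$sequence), ]  # TMT-A value wins for PON1
  hit <- intersect(names(fc), disc$sequence)
  fc[hit] <- disc$fold_change[match(hit, disc$sequence)]
  fc["DGQLLPSSNYSNIK"] <- disc$fold_change[disc$sequence == "NISSEEK"]
  fc
}

# Default planted aggressive-vs-indolent fold-changes: a moderate 1.2x
# increase on the panel peptides of the proteins reported in the
# aggressiveness predictor.
default_ag_fold_changes <- function(fc_ag = 1.2) {
  panel <- glyco_fixture("final_panel")
  genes <- c("FCN3", "LGALS3BP", "AZU1", "C6", "LAMB1", "CHL1", "POSTN")
  fc <- setNames(rep(1, nrow(panel)), panel$sequence)
  fc[panel$gene %in% genes] <- fc_ag
  fc
}

#' Signal configuration for the synthetic PRM run generator
#'
#' Describes the measurement model of the verification phase. Each LC-MS
#' run observes, for every target peptide, a light (endogenous) area
#' equal to baseline x group fold-change x biological factor x
#' per-run enrichment-recovery factor x measurement noise; a heavy
#' (internal-standard) area equal to the spike level times noise -- the
#' standards are added *after* glycopeptide enrichment, so no enrichment
#' factor applies to them; and 30 reference-glycopeptide areas scaled by
#' the same enrichment factor, whose sum is the run's recovery readout.
#'
#' Peptide baseline abundances are drawn log-uniformly across five orders
#' of magnitude, mirroring the dynamic range of the measured panel.
#' Injected discordant pairs scale one replicate's enrichment factor so
#' the pair's scaled relative difference lands just above 0.6,
#' deterministically violating the 0.50 concordance rule; injected
#' low-recovery runs scale the enrichment factor to 5%.
#'
#' @param panel Target panel data frame (`sequence`, `quant_mode`);
#'   default the packaged final panel.
#' @param fold_changes Named vector of planted case/control fold-changes
#'   per panel peptide (> 0); defaults to the discovery-table values.
#' @param ag_fold_changes Named vector of planted aggressive/indolent
#'   fold-changes applied within the cancer group.
#' @param reference_ids Identifiers of the normalization glycopeptides
#'   (default the packaged synthetic 30).
#' @param baseline_range,reference_range Ranges (area units) for the
#'   log-uniform peptide and reference baselines.
#' @param enrichment_cv Lognormal sd of the per-run enrichment recovery
#'   factor (default 0.25).
#' @param heavy_spike_cv Lognormal sd of the heavy-spike level per run
#'   (default 0.05).
#' @param measurement_cv Lognormal sd of per-area measurement noise
#'   (default 0.10).
#' @param biological_cv Lognormal sd of per-subject biological variation
#'   of target peptides (default 0.30, a typical inter-individual CV for
#'   serum proteins).
#' @param reference_biological_cv Biological sd of the reference
#'   glycopeptides (default 0.10; they are chosen to be stable).
#' @param frac_discordant_runs Fraction of samples given an injected
#'   discordant replicate pair.
#' @param frac_low_recovery_runs Fraction of runs given an injected
#'   enrichment failure.
#' @param duplicate If `TRUE` (default) every sample is measured in two
#'   technical replicates.
#' @return A list of class `signal_config`.
#' @export
signal_config <- function(panel = glyco_fixture("final_panel"),
                          fold_changes = default_fold_changes(),
                          ag_fold_changes = default_ag_fold_changes(),
                          reference_ids = glyco_fixture("reference_panel")$peptide_id,
                          baseline_range = c(1e4, 1e9),
                          reference_range = c(1e8, 1e9),
                          enrichment_cv = 0.25,
                          heavy_spike_cv = 0.05,
                          measurement_cv = 0.10,
                          biological_cv = 0.30,
                          reference_biological_cv = 0.10,
                          frac_discordant_runs = 0.10,
                          frac_low_recovery_runs = 0.02,
                          duplicate = TRUE) {
  if (any(!is.finite(fold_changes) | fold_changes <= 0)) {
    stopf("fold-changes must be > 0")
  }
  unknown <- setdiff(names(fold_changes), panel$sequence)
  if (length(unknown)) {
    stopf("fold-changes name peptides absent from the panel: %s",
          paste(unknown, collapse = ", "))
  }
  cvs <- c(enrichment_cv, heavy_spike_cv, measurement_cv, biological_cv,
           reference_biological_cv)
  if (any(cvs < 0)) stopf("CV parameters must be >= 0")
  fr <- c(frac_discordant_runs, frac_low_recovery_runs)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0, 1]")
  structure(list(panel = panel, fold_changes = fold_changes,
                 ag_fold_changes = ag_fold_changes,
                 reference_ids = reference_ids,
                 baseline_range = baseline_range,
                 reference_range = reference_range,
                 enrichment_cv = enrichment_cv,
                 heavy_spike_cv = heavy_spike_cv,
                 measurement_cv = measurement_cv,
                 biological_cv = biological_cv,
                 reference_biological_cv = reference_biological_cv,
                 frac_discordant_runs = frac_discordant_runs,
                 frac_low_recovery_runs = frac_low_recovery_runs,
                 duplicate = isTRUE(duplicate)),
            class = "signal_config")
}

# Enrichment-factor ratio between replicates that yields a target SRD.
srd_target_ratio <- function(srd) (2 + srd * sqrt(2)) / (2 - srd * sqrt(2))

#' Generate synthetic PRM runs for a cohort
#'
#' Produces the long-format run table of a verification experiment: one
#' or two technical replicates per sample, each carrying light and heavy
#' target-peptide areas and the 30 reference-glycopeptide areas, under
#' the measurement model of [signal_config()]. The ground truth (planted
#' fold-changes, baselines, per-run enrichment factors, injected
#' discordant pairs and low-recovery runs) is attached as
#' `attr(runs, "truth")`.
#'
#' @param samples Cohort data frame from [generate_cohort()].
#' @param signal A [signal_config()].
#' @param seed Integer seed.
#' @param enrichment_factors Optional samples x replicates matrix
#'   overriding the drawn enrichment factors (used to probe the scaling
#'   contract: scaling one run's factor by k scales its light and
#'   reference areas by k and leaves heavy areas untouched).
#' @return Data frame with columns `sample_id`, `replicate_idx`,
#'   `peptide_id`, `channel` (`light`, `heavy`, `reference`), `area`,
#'   with the truth sidecar as an attribute.
#' @export
generate_prm_runs <- function(samples, signal = signal_config(), seed = 1,
                              enrichment_factors = NULL) {
  stopifnot(inherits(signal, "signal_config"))
  if (is.null(samples) || nrow(samples) == 0L) stopf("`samples` is empty")
  with_seed(seed, {
    panel <- signal$panel
    peptides <- panel$sequence
    n_pep <- length(peptides)
    is_mode <- panel$quant_mode == "is"
    refs <- signal$reference_ids
    n_ref <- length(refs)
    n_samp <- nrow(samples)
    n_rep <- if (signal$duplicate) 2L else 1L

    baselines <- setNames(
      10^runif(n_pep, log10(signal$baseline_range[1]),
               log10(signal$baseline_range[2])), peptides)
    ref_baselines <- setNames(
      10^runif(n_ref, log10(signal$reference_range[1]),
               log10(signal$reference_range[2])), refs)
    spikes <- baselines  # heavy mix matched to expected endogenous levels

    fc <- setNames(rep(1, n_pep), peptides)
    fc[names(signal$fold_changes)] <- signal$fold_changes
    fc_ag <- setNames(rep(1, n_pep), peptides)
    fc_ag[names(signal$ag_fold_changes)] <- signal$ag_fold_changes

    if (is.null(enrichment_factors)) {
      E <- matrix(rlnorm(n_samp * n_rep, 0, signal$enrichment_cv),
                  n_samp, n_rep)
    } else {
      E <- as.matrix(enrichment_factors)
      stopifnot(nrow(E) == n_samp, ncol(E) == n_rep)
    }

    # Injected failures (recorded in the truth sidecar).
    n_disc <- if (n_rep == 2L) floor(signal$frac_discordant_runs * n_samp) else 0L
    disc_idx <- if (n_disc > 0) sort(sample.int(n_samp, n_disc)) else integer(0)
    if (length(disc_idx) && is.null(enrichment_factors)) {
      E[disc_idx, 2L] <- E[disc_idx, 1L] / srd_target_ratio(0.6)
    }
    run_grid <- expand.grid(sample = seq_len(n_samp), rep = seq_len(n_rep))
    # at most one injected failure per sample, so no sample can lose its
    # entire record to the planted failures (every subject stays
    # analyzable, as in the emulated design)
    eligible <- which(!(run_grid$sample %in% disc_idx))
    n_low <- floor(signal$frac_low_recovery_runs * nrow(run_grid))
    low_idx <- if (n_low > 0 && length(eligible)) {
      shuffled <- sample(eligible)
      picked <- shuffled[!duplicated(run_grid$sample[shuffled])]
      sort(picked[seq_len(min(n_low, length(picked)))])
    } else integer(0)
    if (length(low_idx) && is.null(enrichment_factors)) {
      E[cbind(run_grid$sample[low_idx], run_grid$rep[low_idx])] <-
        E[cbind(run_grid$sample[low_idx], run_grid$rep[low_idx])] * 0.05
    }

    is_pca <- samples$diagnosis == "PCa"
    is_ag <- !is.na(samples$aggressiveness) & samples$aggressiveness == "AG"

    out <- vector("list", n_samp * n_rep)
    k <- 0L
    for (i in seq_len(n_samp)) {
      bio <- rlnorm(n_pep, 0, signal$biological_cv)
      ref_bio <- rlnorm(n_ref, 0, signal$reference_biological_cv)
      truth_level <- baselines * bio *
        (if (is_pca[i]) fc else 1) * (if (is_ag[i]) fc_ag else 1)
      for (r in seq_len(n_rep)) {
        e <- E[i, r]
        light <- truth_level * e * rlnorm(n_pep, 0, signal$measurement_cv)
        heavy <- spikes[is_mode] * rlnorm(sum(is_mode), 0, signal$heavy_spike_cv) *
          rlnorm(sum(is_mode), 0, signal$measurement_cv)
        ref_area <- ref_baselines * ref_bio * e *
          rlnorm(n_ref, 0, signal$measurement_cv)
        k <- k + 1L
        out[[k]] <- data.frame(
          sample_id = samples$sample_id[i],
          replicate_idx = r,
          peptide_id = c(peptides, peptides[is_mode], refs),
          channel = rep(c("light", "heavy", "reference"),
                        c(n_pep, sum(is_mode), n_ref)),
          area = c(light, heavy, ref_area),
          stringsAsFactors = FALSE)
      }
    }
    runs <- do.call(rbind, out)
    rownames(runs) <- NULL
    attr(runs, "truth") <- list(
      baselines = baselines, reference_baselines = ref_baselines,
      fold_changes = fc, ag_fold_changes = fc_ag, spikes = spikes,
      enrichment = E,
      discordant_samples = samples$sample_id[disc_idx],
      low_recovery_runs = data.frame(
        sample_id = samples$sample_id[run_grid$sample[low_idx]],
        replicate_idx = run_grid$rep[low_idx],
        stringsAsFactors = FALSE))
    runs
  })
}

#' Generate a synthetic discovery-phase candidate table
#'
#' Fixture generator for the candidate filter: builds `n_peptides` rows
#' of which exactly `n_significant` satisfy every rule of the supplied
#' [filter_policy()] (fold-change above threshold, p-value below the cap,
#' sequon present, length and missed cleavages within limits); every
#' other row violates exactly one randomly chosen rule. The planted truth
#' is the logical column `is_significant`.
#'
#' @param n_peptides,n_significant Row counts with
#'   `n_significant <= n_peptides`.
#' @param fc_range Fold-change range for the significant rows; the lower
#'   bound must reach the policy's `fc_min`.
#' @param seed Integer seed.
#' @param policy A [filter_policy()].
#' @return Data frame with columns `sequence`, `gene`, `fold_change`,
#'   `p_value`, `literature_flag`, `glyco_site`, `is_significant`.
#' @export
generate_discovery_table <- function(n_peptides, n_significant,
                                     fc_range = c(1.2, 2.5), seed = 1,
                                     policy = filter_policy()) {
  assert_positive_count(n_peptides, "n_peptides")
  assert_positive_count(n_significant, "n_significant")
  if (n_significant > n_peptides) stopf("n_significant must be <= n_peptides")
  if (length(fc_range) != 2L || fc_range[2] < fc_range[1]) {
    stopf("`fc_range` must be c(lo, hi) with lo <= hi")
  }
  if (fc_range[1] < policy$fc_min) {
    stopf("fc_range lower bound must reach the policy fc_min")
  }
  with_seed(seed, {
    # Residues that can never create a sequon or a cleavage site.
    neutral <- setdiff(AA_ALPHABET, c("N", "K", "R", "P"))
    base_seq <- function(len) paste(sample(neutral, len, replace = TRUE),
                                    collapse = "")
    with_sequon <- function(len) {
      chars <- sample(neutral, len, replace = TRUE)
      pos <- sample.int(len - 2L, 1L)
      chars[pos] <- "N"; chars[pos + 2L] <- "T"
      paste0(paste(chars, collapse = ""), "K")
    }
    rows <- vector("list", n_peptides)
    for (i in seq_len(n_peptides)) {
      if (i <= n_significant) {
        rows[[i]] <- data.frame(
          sequence = with_sequon(sample(7:min(20L, policy$max_length - 2L), 1L)),
          fold_change = runif(1, max(fc_range[1], policy$fc_min), fc_range[2]),
          p_value = runif(1, 1e-4, policy$p_max * 0.99),
          is_significant = TRUE, stringsAsFactors = FALSE)
      } else {
        violation <- sample(c("p_value", "fold_change", "sequon", "length",
                              "missed_cleavages"), 1L)
        seqn <- switch(violation,
          sequon = paste0(base_seq(sample(7:15, 1L)), "K"),
          length = with_sequon(policy$max_length + sample(1:6, 1L)),
          missed_cleavages = {  # inject max+1 internal cleavage sites
            s <- with_sequon(sample(10:15, 1L))
            body <- substr(s, 1, nchar(s) - 1L)
            paste0(body,
                   paste(rep("KA", policy$max_missed_cleavages + 1L),
                         collapse = ""), "K")
          },
          with_sequon(sample(7:15, 1L)))
        rows[[i]] <- data.frame(
          sequence = seqn,
          fold_change = if (violation == "fold_change") {
            runif(1, 0.5, policy$fc_rescue_min * 0.99)
          } else runif(1, max(fc_range[1], policy$fc_min), fc_range[2]),
          p_value = if (violation == "p_value") {
            runif(1, policy$p_max, 1)
          } else runif(1, 1e-4, policy$p_max * 0.99),
          is_significant = FALSE, stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    # Disambiguate rare sequence collisions by prepending a neutral residue
    # (leaves sequon, cleavage and significance status intact).
    while (anyDuplicated(tab$sequence)) {
      dup <- duplicated(tab$sequence)
      tab$sequence[dup] <- paste0(sample(neutral, sum(dup), replace = TRUE),
                                  tab$sequence[dup])
    }
    tab$gene <- sprintf("G%04d", seq_len(n_peptides))
    tab$literature_flag <- FALSE
    tab$glyco_site <- NA_integer_
    tab[, c("sequence", "gene", "fold_change", "p_value", "literature_flag",
            "glyco_site", "is_significant")]
  })
}

#' Write a simulated dataset to disk
#'
#' Writes the PRM run table as TSV, the clinical table as CSV, and the
#' truth sidecar (planted fold-changes and injected failures) as TSVs.
#'
#' @param runs Run table from [generate_prm_runs()].
#' @param samples Cohort table from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(runs, samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(runs = file.path(dir, "prm_runs.tsv"),
             clinical = file.path(dir, "clinical.csv"),
             truth_fc = file.path(dir, "truth_fold_changes.tsv"),
             truth_fail = file.path(dir, "truth_exclusions.tsv"))
  write.table(runs, files["runs"], sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(samples, files["clinical"], row.names = FALSE)
  truth <- attr(runs, "truth")
  if (!is.null(truth)) {
    write.table(data.frame(peptide_id = names(truth$fold_changes),
                           fold_change = truth$fold_changes,
                           ag_fold_change = truth$ag_fold_changes,
                           baseline = truth$baselines),
                files["truth_fc"], sep = "\t", row.names = FALSE, quote = FALSE)
    fail <- rbind(
      data.frame(sample_id = truth$discordant_samples,
                 replicate_idx = rep(2L, length(truth$discordant_samples)),
                 kind = rep("discordant", length(truth$discordant_samples)),
                 stringsAsFactors = FALSE),
      data.frame(truth$low_recovery_runs,
                 kind = rep("low_recovery", nrow(truth$low_recovery_runs))))
    write.table(fail, files["truth_fail"], sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  invisible(files)
}
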