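# Default per-group clinical distributions: median and interquartile
# bounds of the study cohort (age in years, prostate dimension in cc,
# proPSA in pg/mL, tPSA and fPSA in ng/mL, ftPSA in %).
default_clinical_params <- function() {
  list(
    PCa = list(age                = c(median = 69,    q1 = 64.5,  q3 = 73.5),
               prostate_dimension = c(median = 40,    q1 = 30,    q3 = 50),
               proPSA             = c(median = 553.9, q1 = 385.7, q3 = 996),
               tPSA               = c(median = 8.05,  q1 = 5.66,  q3 = 15.85),
               fPSA               = c(median = 1.43,  q1 = 0.99,  q3 = 2.7),
               ftPSA              = c(median = 16,    q1 = 12,    q3 = 22)),
    BPH = list(age                = c(median = 69,    q1 = 62,    q3 = 72.5),
               prostate_dimension = c(median = 55,    q1 = 40,    q3 = 78),
               proPSA             = c(median = 257.7, q1 = 87,    q3 = 440),
               tPSA               = c(median = 2.4,   q1 = 0.93,  q3 = 4.84),
               fPSA               = c(median = 0.81,  q1 = 0.28,  q3 = 1.72),
               ftPSA              = c(median = 35,    q1 = 24,    q3 = 45))
  )
}

#' Cohort configuration for the synthetic study generator
#'
#' Defines the case/control design of a simulated serum cohort: group
#' sizes, the aggressive / non-aggressive split within the cancer group
#' (Gleason 3+3 defines NAG, anything higher AG), and per-group clinical
#' distributions given as median plus interquartile bounds. Clinical
#' markers are simulated as lognormal variables parameterized to match
#' the configured median and IQR (strictly positive, right-skewed, as
#' such markers are in practice).
#'
#' @param n_pca,n_bph Group sizes (default 79 cancer / 84 benign).
#' @param n_nag Number of non-aggressive (Gleason 3+3) cancer samples;
#'   `n_ag` is the remainder. Defaults reproduce the 53/26 split.
#' @param n_ag Number of aggressive cancer samples; must satisfy
#'   `n_ag + n_nag == n_pca`.
#' @param clinical_params Nested list `group -> variable -> c(median, q1,
#'   q3)`; see `glycoPRM:::default_clinical_params()`. The configured
#'   ftPSA entry is reference-only: ftPSA is derived as `100 * fPSA /
#'   tPSA` times lognormal noise so that the ratio stays consistent with
#'   its parts.
#' @param gleason_weights Relative frequencies of the AG Gleason strata
#'   `3+4`, `4+3`, `>=8` (defaults 22/16/15).
#' @param ag_propsa_fc Multiplicative proPSA shift applied to AG samples
#'   (default 1.2), the planted clinical signal of the aggressiveness
#'   sub-analysis.
#' @param ftpsa_noise_cv Lognormal sd of the ftPSA consistency noise.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_pca = 79, n_bph = 84, n_nag = 26,
                          n_ag = n_pca - n_nag,
                          clinical_params = default_clinical_params(),
                          gleason_weights = c("3+4" = 22, "4+3" = 16, ">=8" = 15),
                          ag_propsa_fc = 1.2,
                          ftpsa_noise_cv = 0.1) {
  assert_positive_count(n_pca, "n_pca")
  assert_positive_count(n_bph, "n_bph")
  assert_positive_count(n_nag, "n_nag")
  assert_positive_count(n_ag, "n_ag")
  if (n_ag + n_nag != n_pca) stopf("n_ag + n_nag must equal n_pca")
  for (grp in names(clinical_params)) {
    for (v in names(clinical_params[[grp]])) {
      p <- clinical_params[[grp]][[v]]
      if (any(p <= 0)) stopf("%s/%s: medians and IQR bounds must be > 0", grp, v)
      if (!(p[["q1"]] <= p[["median"]] && p[["median"]] <= p[["q3"]])) {
        stopf("%s/%s: IQR bounds must be ordered q1 <= median <= q3", grp, v)
      }
    }
  }
  structure(list(n_pca = n_pca, n_bph = n_bph, n_nag = n_nag, n_ag = n_ag,
                 clinical_params = clinical_params,
                 gleason_weights = gleason_weights,
                 ag_propsa_fc = ag_propsa_fc,
                 ftpsa_noise_cv = ftpsa_noise_cv),
            class = "cohort_config")
}

# Lognormal draw matching a target median and interquartile range:
# meanlog = log(median), sdlog = log(q3/q1) / (2 * qnorm(0.75)).
rlnorm_median_iqr <- function(n, params) {
  sdlog <- if (params[["q3"]] > params[["q1"]]) {
    log(params[["q3"]] / params[["q1"]]) / (2 * qnorm(0.75))
  } else 0
  rlnorm(n, meanlog = log(params[["median"]]), sdlog = sdlog)
}

#' Generate a synthetic clinical cohort
#'
#' Draws one sample record per subject: diagnosis label, Gleason stratum
#' for cancer samples, and the clinical variables age, prostate
#' dimension, proPSA, tPSA, fPSA and ftPSA. All positive markers are
#' lognormal with group medians/IQRs converging to the configured values;
#' ftPSA is derived from fPSA and tPSA up to the configured noise.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same seed and config reproduce the
#'   cohort exactly.
#' @return Data frame with one row per sample (`sample_id`, `diagnosis`,
#'   `gleason`, `aggressiveness`, clinical columns).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' table(cohort$diagnosis)  # 79 PCa, 84 BPH
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    n <- config$n_pca + config$n_bph
    diagnosis <- rep(c("PCa", "BPH"), c(config$n_pca, config$n_bph))
    gleason <- rep(NA_character_, n)
    aggressiveness <- rep(NA_character_, n)
    if (config$n_pca > 0) {
      strata <- character(config$n_pca)
      strata[seq_len(config$n_nag)] <- "3+3"
      if (config$n_ag > 0) {
        w <- config$gleason_weights / sum(config$gleason_weights)
        strata[config$n_nag + seq_len(config$n_ag)] <-
          sample(names(w), config$n_ag, replace = TRUE, prob = w)
      }
      strata <- sample(strata)  # shuffle within the PCa block
      gleason[diagnosis == "PCa"] <- strata
      aggressiveness[diagnosis == "PCa"] <- ifelse(strata == "3+3", "NAG", "AG")
    }

    draw_var <- function(varname) {
      out <- numeric(n)
      for (grp in c("PCa", "BPH")) {
        idx <- which(diagnosis == grp)
        if (length(idx)) {
          out[idx] <- rlnorm_median_iqr(length(idx),
                                        config$clinical_params[[grp]][[varname]])
        }
      }
      out
    }
    age <- draw_var("age")
    prostate_dimension <- draw_var("prostate_dimension")
    proPSA <- draw_var("proPSA")
    tPSA <- draw_var("tPSA")
    fPSA <- draw_var("fPSA")
    ag <- !is.na(aggressiveness) & aggressiveness == "AG"
    proPSA[ag] <- proPSA[ag] * config$ag_propsa_fc
    ftPSA <- 100 * fPSA / tPSA *
      rlnorm(n, meanlog = 0, sdlog = config$ftpsa_noise_cv)

    data.frame(sample_id = sprintf("S%03d", seq_len(n)),
               diagnosis = diagnosis, gleason = gleason,
               aggressiveness = aggressiveness, age = age,
               prostate_dimension = prostate_dimension, proPSA = proPSA,
               tPSA = tPSA, fPSA = fPSA, ftPSA = ftPSA,
               stringsAsFactors = FALSE)
  })
}
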