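#' Partition a cohort into grey-zone holdout, training and test sets
#'
#' Reserves `holdout_greyzone` samples drawn from the diagnostic grey
#' zone (tPSA between 4 and 10 ng/mL, where PSA alone is least
#' informative) for ensemble-voting evaluation; the remaining
#' model-building samples are split into training and test sets,
#' stratified by label, with `floor(train_frac * n)` training samples
#' allocated across strata by largest remainder.
#'
#' @param samples Data frame with `sample_id`, the label column and the
#'   tPSA column.
#' @param holdout_greyzone Grey-zone holdout size (default 20); an error
#'   is raised if fewer samples are eligible.
#' @param train_frac Training fraction of the model-building set
#'   (default 0.70).
#' @param seed Integer seed.
#' @param label_col,tpsa_col Column names (defaults `"diagnosis"`,
#'   `"tPSA"`).
#' @param greyzone_range tPSA window defining eligibility, default
#'   `c(4, 10)`.
#' @return List of `sample_id` vectors: `greyzone`, `train`, `test`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 1)
#' sp <- split_cohort(cohort, seed = 1)
#' lengths(sp)  # 20 greyzone, 100 train, 43 test
split_cohort <- function(samples, holdout_greyzone = 20, train_frac = 0.7,
                         seed = 1, label_col = "diagnosis", tpsa_col = "tPSA",
                         greyzone_range = c(4, 10)) {
  assert_positive_count(holdout_greyzone, "holdout_greyzone")
  if (!(train_frac > 0 && train_frac < 1)) stopf("`train_frac` must be in (0, 1)")
  with_seed(seed, {
    tpsa <- samples[[tpsa_col]]
    eligible <- samples$sample_id[tpsa >= greyzone_range[1] &
                                  tpsa <= greyzone_range[2]]
    if (length(eligible) < holdout_greyzone) {
      stopf("only %d grey-zone-eligible samples for a holdout of %d",
            length(eligible), holdout_greyzone)
    }
    greyzone <- sort(sample(eligible, holdout_greyzone))
    build <- samples[!(samples$sample_id %in% greyzone), ]
    split <- stratified_split(build$sample_id, build[[label_col]],
                              train_frac)
    list(greyzone = greyzone, train = split$train, test = split$test)
  })
}

# Stratified train/test split: floor(frac * n) training samples in total,
# allocated across label strata by largest remainder. Consumes the RNG.
stratified_split <- function(ids, labels, train_frac) {
  n <- length(ids)
  n_train <- floor(train_frac * n)
  strata <- split(ids, labels)
  quota <- n_train * lengths(strata) / n
  base <- floor(quota)
  extra <- order(-(quota - base))
  need <- n_train - sum(base)
  if (need > 0) base[extra[seq_len(need)]] <- base[extra[seq_len(need)]] + 1L
  train <- unlist(lapply(seq_along(strata), function(k) {
    sample(strata[[k]], base[k])
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(ids, train)))
}
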