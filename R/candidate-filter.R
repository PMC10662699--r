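#' Discovery-phase candidate filter policy
#'
#' Thresholds for retaining differential formerly N-glycosylated peptides
#' from a discovery experiment. A peptide is retained when its p-value is
#' below `p_max`, a glycosylation sequon is present, its length and
#' missed-cleavage count do not exceed the assay-suitability limits, and
#' its fold-change (case group over control group) is at least `fc_min` --
#' or at least `fc_rescue_min` when the corresponding protein has prior
#' literature support (`literature_flag`), the "rescue" branch used to
#' admit modest fold-changes from the more precise labelling workflow.
#'
#' @param p_max Maximum p-value (exclusive), default 0.1.
#' @param fc_min Fold-change threshold (inclusive), default 1.2.
#' @param fc_rescue_min Rescue fold-change threshold (inclusive) for
#'   literature-supported peptides, default 1.08.
#' @param max_length Maximum peptide length, default 25.
#' @param max_missed_cleavages Maximum tryptic missed cleavages, default 2
#'   (the database-search allowance; retained discovery candidates include
#'   peptides with one internal K).
#' @param require_sequon Require an N-X-S/T sequon, default `TRUE`.
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(p_max = 0.1, fc_min = 1.2, fc_rescue_min = 1.08,
                          max_length = 25, max_missed_cleavages = 2,
                          require_sequon = TRUE) {
  if (!(p_max > 0 && p_max < 1)) stopf("`p_max` must lie in (0, 1)")
  if (!(fc_rescue_min > 0 && fc_rescue_min < fc_min)) {
    stopf("need 0 < fc_rescue_min < fc_min")
  }
  assert_positive_count(max_length, "max_length")
  assert_positive_count(max_missed_cleavages, "max_missed_cleavages")
  structure(list(p_max = p_max, fc_min = fc_min,
                 fc_rescue_min = fc_rescue_min, max_length = max_length,
                 max_missed_cleavages = max_missed_cleavages,
                 require_sequon = isTRUE(require_sequon)),
            class = "filter_policy")
}

# Sequon presence for one row: annotated site wins, else peptide-level scan.
row_has_sequon <- function(sequence, glyco_site) {
  if (!is.na(glyco_site) && glyco_site >= 1 && glyco_site <= nchar(sequence)) {
    return(TRUE)
  }
  length(find_sequons(sequence)) > 0L
}

#' Filter discovery candidates
#'
#' Applies a [filter_policy()] to a table of candidate peptides. Rules are
#' checked in the order p-value, sequon, length, missed cleavages,
#' fold-change; each rejected row is annotated with the first failing
#' rule.
#'
#' @param table Data frame with columns `sequence`, `fold_change`,
#'   `p_value`; optional `literature_flag` (default `FALSE`) and
#'   `glyco_site` (annotated 1-based glycosylation position, used as the
#'   sequon evidence when present -- a sequon can complete beyond the
#'   tryptic boundary and then is invisible to the peptide-level scan).
#' @param policy A [filter_policy()].
#' @return A list with `retained` (the surviving rows) and `rejections`
#'   (data frame of `sequence`, `reason` with reason in `p_value`,
#'   `sequon`, `length`, `missed_cleavages`, `fold_change`).
#' @export
filter_candidates <- function(table, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (is.null(table) || nrow(table) == 0L) {
    return(list(retained = table,
                rejections = data.frame(sequence = character(0),
                                        reason = character(0))))
  }
  need <- c("sequence", "fold_change", "p_value")
  miss <- setdiff(need, names(table))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  lit <- if ("literature_flag" %in% names(table)) table$literature_flag else FALSE
  lit <- rep_len(as.logical(lit), nrow(table))
  site <- if ("glyco_site" %in% names(table)) table$glyco_site else NA_integer_
  site <- rep_len(site, nrow(table))
  if (any(!is.finite(table$fold_change) | table$fold_change <= 0)) {
    stopf("fold_change must be > 0")
  }
  if (any(!is.finite(table$p_value) | table$p_value <= 0 | table$p_value > 1)) {
    stopf("p_value must lie in (0, 1]")
  }

  reason <- rep(NA_character_, nrow(table))
  for (i in seq_len(nrow(table))) {
    seq_i <- table$sequence[i]
    if (table$p_value[i] >= policy$p_max) {
      reason[i] <- "p_value"
    } else if (policy$require_sequon && !row_has_sequon(seq_i, site[i])) {
      reason[i] <- "sequon"
    } else if (nchar(seq_i) > policy$max_length) {
      reason[i] <- "length"
    } else if (count_missed_cleavages(seq_i) > policy$max_missed_cleavages) {
      reason[i] <- "missed_cleavages"
    } else if (!(table$fold_change[i] >= policy$fc_min ||
                 (lit[i] && table$fold_change[i] >= policy$fc_rescue_min))) {
      reason[i] <- "fold_change"
    }
  }
  keep <- is.na(reason)
  retained <- table[keep, , drop = FALSE]
  retained$rescued <- retained$fold_change < policy$fc_min
  rownames(retained) <- NULL
  list(retained = retained,
       rejections = data.frame(sequence = table$sequence[!keep],
                               reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

#' Merge candidate lists from several discovery experiments
#'
#' Deduplicated union keyed by peptide sequence with provenance: a peptide
#' selected by more than one experiment appears once, its
#' `source_experiments` field recording every source. Conflicting gene
#' annotations for an identical sequence raise an error.
#'
#' @param ... Data frames, each with columns `sequence`, `gene` and
#'   (optionally) `source_experiment`; each list must be internally unique
#'   by sequence.
#' @return Data frame keyed by sequence with a `source_experiments`
#'   column (`";"`-separated).
#' @export
#' @examples
#' a <- glyco_fixture("tmta"); b <- glyco_fixture("tmtb")
#' nrow(merge_candidate_lists(a, b))  # 16: HANWTLTPLK shared
merge_candidate_lists <- function(...) {
  lists <- list(...)
  lists <- lists[!vapply(lists, is.null, logical(1))]
  if (!length(lists)) stopf("no candidate lists supplied")
  for (k in seq_along(lists)) {
    l <- lists[[k]]
    if (anyDuplicated(l$sequence)) {
      stopf("list %d is not unique by sequence", k)
    }
    if (!"source_experiment" %in% names(l)) {
      l$source_experiment <- paste0("list", k)
    }
    lists[[k]] <- l
  }
  all_rows <- do.call(rbind, lapply(lists, function(l) {
    data.frame(sequence = l$sequence, gene = l$gene,
               source_experiment = l$source_experiment,
               stringsAsFactors = FALSE)
  }))
  merged <- list()
  for (i in seq_len(nrow(all_rows))) {
    s <- all_rows$sequence[i]
    if (is.null(merged[[s]])) {
      merged[[s]] <- all_rows[i, ]
    } else {
      if (merged[[s]]$gene != all_rows$gene[i]) {
        stopf("conflicting gene annotation for %s: %s vs %s",
              s, merged[[s]]$gene, all_rows$gene[i])
      }
      src <- unique(unlist(strsplit(
        c(merged[[s]]$source_experiment, all_rows$source_experiment[i]), ";")))
      merged[[s]]$source_experiment <- paste(sort(src), collapse = ";")
    }
  }
  out <- do.call(rbind, merged)
  names(out)[names(out) == "source_experiment"] <- "source_experiments"
  rownames(out) <- NULL
  out
}
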