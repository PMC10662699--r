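#' Packaged study tables
#'
#' Accessor for the candidate tables and panels shipped with the package:
#' the discovery-phase candidate lists from the two isobaric-labelling
#' experiments (`"tmta"`, `"tmtb"`) and the label-free deep-fractionation
#' experiment (`"d3"`), the merged 34-peptide PRM candidate list
#' (`"prm_candidates"`), the final verification panel of 31 formerly
#' N-glycosylated peptides with their quantification mode
#' (`"final_panel"`), the printed five-selector boolean grid of retained
#' variables (`"selection_grid"`), and a synthetic stand-in list of the 30
#' high-abundance reference glycopeptides used for enrichment
#' normalization (`"reference_panel"`; the study's own reference list is
#' not public, so these are placeholder identifiers REF01..REF30).
#'
#' @param name Table name, one of `"tmta"`, `"tmtb"`, `"d3"`,
#'   `"prm_candidates"`, `"final_panel"`, `"selection_grid"`,
#'   `"reference_panel"`.
#' @return A `data.frame` with the columns of the corresponding table.
#'   Fold-change and p-value columns are present only for the two TMT
#'   tables; `glyco_site` is the annotated 1-based position of the
#'   glycosylated asparagine (the motif of three peptides completes beyond
#'   the tryptic C-terminus, so a peptide-level sequon scan does not see
#'   it -- this is why the annotation is carried explicitly).
#' @export
#' @examples
#' nrow(glyco_fixture("prm_candidates"))  # 34 candidate peptides
glyco_fixture <- function(name = c("tmta", "tmtb", "d3", "prm_candidates",
                                   "final_panel", "selection_grid",
                                   "reference_panel")) {
  name <- match.arg(name)
  file <- switch(name,
    tmta = "tmta_candidates.tsv",
    tmtb = "tmtb_candidates.tsv",
    d3 = "d3_candidates.tsv",
    prm_candidates = "prm_candidates.tsv",
    final_panel = "final_panel.tsv",
    selection_grid = "selection_grid.tsv",
    reference_panel = "reference_panel_synthetic.tsv"
  )
  path <- system.file("extdata", file, package = "glycoPRM", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (name == "selection_grid") {
    tab$total <- rowSums(tab[, setdiff(names(tab), "variable")])
  }
  tab
}
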