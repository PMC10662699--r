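AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_sequence <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence) || is.na(sequence)) {
    stopf("`sequence` must be a single string")
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(chars, AA_ALPHABET)
  if (length(bad)) {
    stopf("invalid residues in sequence '%s': %s (uppercase one-letter codes only)",
          sequence, paste(unique(bad), collapse = ", "))
  }
  chars
}

#' Find N-glycosylation sequons in a peptide
#'
#' Scans an uppercase one-letter amino-acid sequence for the
#' N-glycosylation consensus motif N-X-S/T. By default the biochemical
#' convention that proline in the X position abolishes glycosylation is
#' applied (`allow_proline = FALSE`).
#'
#' Note that a sequon whose S/T falls beyond the peptide's C-terminus
#' (i.e. in the protein but not the tryptic peptide) cannot be seen by
#' this peptide-level scan; curated tables therefore carry the annotated
#' site alongside the sequence.
#'
#' @param sequence Peptide sequence (uppercase one-letter codes).
#' @param allow_proline If `TRUE`, N-P-S/T also counts as a sequon.
#' @return Integer vector of 1-based positions of the asparagine of each
#'   motif occurrence; `integer(0)` if none.
#' @export
#' @examples
#' find_sequons("SNSSMHITDCR")  # 2
#' find_sequons("NPSA")         # none: proline in X position
find_sequons <- function(sequence, allow_proline = FALSE) {
  chars <- check_sequence(sequence)
  n <- length(chars)
  if (n < 3L) return(integer(0))
  i <- seq_len(n - 2L)
  hit <- chars[i] == "N" & chars[i + 2L] %in% c("S", "T")
  if (!allow_proline) hit <- hit & chars[i + 1L] != "P"
  which(hit)
}

#' Count tryptic missed cleavages
#'
#' Counts internal K/R residues not followed by proline (the trypsin
#' cleavage convention). The C-terminal residue never counts: a peptide
#' ending in K or R is fully cleaved.
#'
#' @param sequence Peptide sequence (uppercase one-letter codes).
#' @return Number of missed cleavage sites.
#' @export
#' @examples
#' count_missed_cleavages("GVNFNVSK")                  # 0
#' count_missed_cleavages("NGSDCPDKFCLFQSETK")         # 1
#' count_missed_cleavages("FVNVTVTPEDQCRPNNVCTGVLTR")  # 0 (R before P)
count_missed_cleavages <- function(sequence) {
  chars <- check_sequence(sequence)
  n <- length(chars)
  if (n < 2L) return(0L)
  i <- seq_len(n - 1L)
  sum(chars[i] %in% c("K", "R") & chars[i + 1L] != "P")
}
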