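#' Smith-Waterman local alignment
#'
#' Local alignment with match +1, mismatch -1 and linear gap penalty -2
#' (open = extend). Identity is computed over alignment columns, gaps
#' included.
#'
#' @param pattern,subject DNA sequences (character scalars).
#' @param match,mismatch,gap Scoring parameters.
#' @return list with `score`, `matches`, `mismatches`, `gaps`, `columns`,
#'   `identity` (matches / columns), 1-based aligned spans
#'   (`pattern_start`/`pattern_end`, `subject_start`/`subject_end`) and
#'   `pattern_coverage` (aligned pattern span / pattern length).
#' @export
sw_align <- function(pattern, subject, match = 1, mismatch = -1, gap = -2) {
  a <- encode_seq(pattern)
  b <- encode_seq(subject)
  r <- .sw_align_cpp(a, b, match, mismatch, gap)
  r$identity <- if (r$columns > 0) r$matches / r$columns else 0
  r$pattern_coverage <- (r$pattern_end - r$pattern_start + 1) / length(a)
  r
}

#' Identify lncRNAs that are putative miRNA precursors
#'
#' Each lncRNA is locally aligned against each known hairpin; a precursor
#' edge is emitted when the alignment identity (matches / alignment columns)
#' strictly exceeds `min_identity` and the aligned region spans at least
#' `min_coverage` of the hairpin, so a short perfect match cannot qualify.
#'
#' @param seqs Named character vector of lncRNA sequences.
#' @param hairpins Named character vector of hairpin reference sequences.
#' @param min_identity Identity threshold, strict (default 0.90).
#' @param min_coverage Minimum fraction of the hairpin covered by the
#'   alignment (default 0.80).
#' @return data.frame of edges: `source` (lncRNA), `target` (hairpin),
#'   `edge_type = "precursor"`, `score` (identity), plus `coverage`.
#' @export
identify_precursors <- function(seqs, hairpins, min_identity = 0.90,
                                min_coverage = 0.80) {
  if (length(hairpins) == 0L) {
    warning("empty hairpin set; no precursors can be identified")
    return(cbind(interaction_edges(), coverage = numeric()))
  }
  rows <- list()
  for (lid in names(seqs)) {
    for (hid in names(hairpins)) {
      al <- sw_align(hairpins[[hid]], seqs[[lid]])
      if (al$pattern_coverage >= min_coverage && al$identity > min_identity) {
        rows[[paste(lid, hid)]] <- data.frame(
          source = lid, target = hid, edge_type = "precursor",
          score = al$identity, coverage = al$pattern_coverage,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else cbind(interaction_edges(), coverage = numeric())
}
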