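#' Measure a repeat-tract length inside read sequences
#'
#' Matches each read against a marker's flanking anchors and returns the
#' length of the repeat run between them. The forward anchor
#' (`flank5 (B)+ flank3`) is tried first; reads that do not match it are tried
#' against the complementary-reverse anchor. The run is maximal: the 3' flank
#' must begin at the first position after the run that is not the repeat base,
#' so an indel inside the tract changes the measured length — which is the
#' signal the method detects. When a read contains several disjoint anchor
#' occurrences the leftmost is used; `N` bases never extend a run.
#'
#' @param read_sequence Character vector of read sequences (uppercase ACGTN).
#' @param marker A single-row marker tibble from [load_marker_table()].
#' @return Integer vector of repeat lengths, `NA` where neither anchor matches.
#' @examples
#' bat25 <- msi_panel()[1, ]
#' match_anchor(paste0("AATTTGA", strrep("T", 25), "GAGAACC"), bat25) # 25
#' match_anchor("ACGTACGT", bat25) # NA
#' @export
match_anchor <- function(read_sequence, marker) {
  stopifnot(nrow(marker) == 1)
  out <- anchor_run_length(read_sequence, marker$flank5, marker$repeat_base,
                           marker$flank3)
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- anchor_run_length(read_sequence[miss], marker$flank5_rc,
                                   marker$repeat_base_rc, marker$flank3_rc)
  }
  out
}

# Possessive quantifier (B++): the run cannot backtrack, so flank3 is required
# at the first non-repeat-base position — maximal-run semantics, leftmost match.
anchor_run_length <- function(reads, flank5, base, flank3) {
  pattern <- paste0(flank5, "(?:", base, "++)", flank3)
  m <- regexpr(pattern, reads, perl = TRUE)
  len <- attr(m, "match.length") - nchar(flank5) - nchar(flank3)
  len[m == -1L] <- NA_integer_
  as.integer(len)
}
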