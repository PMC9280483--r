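#' Load a marker definition table
#'
#' Reads a tab-separated marker table with columns `name`, `position`
#' (`chrom:start-end`, 1-based inclusive), `anchor`, `anchor_cr` and
#' `repeat_length`. Anchors use the notation `FLANK5(B+)FLANK3`, where `B` is
#' the repeated base; the complementary-reverse (CR) anchor must equal the
#' reverse complement of the forward anchor, decomposed the same way. This is
#' verified at load time so a typo in either anchor is caught before any read
#' is matched.
#'
#' @param path Path to the marker TSV. Defaults to the bundled six-marker
#'   mononucleotide panel (Bat25, Bat26, Mono27, NR21, NR24, NR27).
#' @return A tibble with one row per marker and columns `name`, `chrom`,
#'   `start`, `end`, `flank5`, `repeat_base`, `flank3`, `flank5_rc`,
#'   `repeat_base_rc`, `flank3_rc`, `ref_repeat_length`.
#' @examples
#' panel <- msi_panel()
#' nrow(panel) # 6
#' @export
load_marker_table <- function(path = msi_panel_path()) {
  if (!file.exists(path)) {
    abort(paste0("marker table not found: ", path), class = "msipeaks_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    position = readr::col_character(),
    anchor = readr::col_character(),
    anchor_cr = readr::col_character(),
    repeat_length = readr::col_integer()
  ))
  required <- c("name", "position", "anchor", "anchor_cr", "repeat_length")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("marker table missing column(s): ", paste(missing, collapse = ", ")),
          class = "msipeaks_parse_error")
  }

  pos <- stringr::str_match(raw$position, "^([^:]+):(\\d+)-(\\d+)$")
  bad <- which(is.na(pos[, 1]))
  if (length(bad) > 0) {
    abort(paste0("malformed position for marker '", raw$name[bad[1]], "': ",
                 raw$position[bad[1]]), class = "msipeaks_parse_error")
  }

  fwd <- parse_anchor(raw$anchor, raw$name)
  crv <- parse_anchor(raw$anchor_cr, raw$name)

  markers <- tibble(
    name = raw$name,
    chrom = pos[, 2],
    start = as.integer(pos[, 3]),
    end = as.integer(pos[, 4]),
    flank5 = fwd$flank5,
    repeat_base = fwd$repeat_base,
    flank3 = fwd$flank3,
    flank5_rc = crv$flank5,
    repeat_base_rc = crv$repeat_base,
    flank3_rc = crv$flank3,
    ref_repeat_length = raw$repeat_length
  )
  validate_markers(markers)
  markers
}

#' @rdname load_marker_table
#' @export
msi_panel <- function() {
  load_marker_table(msi_panel_path())
}

#' Path to the bundled default marker panel
#' @return File path of the six-marker panel TSV shipped with the package.
#' @export
msi_panel_path <- function() {
  system.file("extdata", "markers.tsv", package = "msipeaks", mustWork = TRUE)
}

# Decompose FLANK5(B+)FLANK3 notation; vectorized, errors name the first bad row.
parse_anchor <- function(anchor, name) {
  m <- stringr::str_match(anchor, "^([ACGT]+)\\(([ACGT])\\+\\)([ACGT]+)$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0) {
    abort(paste0("malformed anchor for marker '", name[bad[1]], "': ", anchor[bad[1]]),
          class = "msipeaks_parse_error")
  }
  list(flank5 = m[, 2], repeat_base = m[, 3], flank3 = m[, 4])
}

validate_markers <- function(markers) {
  with(markers, {
    if (any(start > end)) {
      abort(paste0("start > end for marker '", name[which(start > end)[1]], "'"),
            class = "msipeaks_validation_error")
    }
  })
  # CR anchor must be the reverse complement of the forward anchor:
  # flank5_rc = revcomp(flank3), base_rc = complement(base), flank3_rc = revcomp(flank5)
  for (i in seq_len(nrow(markers))) {
    m <- markers[i, ]
    ok <- identical(m$flank5_rc, revcomp(m$flank3)) &&
      identical(m$repeat_base_rc, revcomp(m$repeat_base)) &&
      identical(m$flank3_rc, revcomp(m$flank5))
    if (!ok) {
      abort(paste0("CR anchor inconsistent with forward anchor for marker '",
                   m$name, "'"), class = "msipeaks_validation_error")
    }
  }
  invisible(markers)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
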