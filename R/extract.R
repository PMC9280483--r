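#' Extract per-marker repeat-length histograms from a BAM file
#'
#' For each marker, fetches reads overlapping the marker region from a
#' coordinate-sorted, indexed BAM, applies the usual alignment filters, and
#' measures each read's repeat-tract length with [match_anchor()]. Unmapped,
#' secondary and supplementary alignments are always skipped; duplicate-flagged
#' reads are skipped when `drop_duplicates` is on (mirroring an upstream
#' `samtools rmdup`); reads below `min_mapq` are skipped. A read contributes at
#' most one count.
#'
#' @param bam Path to an indexed, coordinate-sorted BAM file.
#' @param markers Marker tibble from [load_marker_table()]; defaults to the
#'   bundled six-marker panel.
#' @param sample_id,tissue Identifiers recorded on every histogram row;
#'   `tissue` is `"tumor"` or `"normal"`.
#' @param min_mapq Minimum mapping quality (default 1).
#' @param drop_duplicates Drop duplicate-flagged reads (default `TRUE`).
#' @return A depth table: tibble with columns `sample_id`, `tissue`, `marker`,
#'   `repeat_length`, `count`, one row per observed length per marker. Markers
#'   with no anchor-matched reads contribute no rows.
#' @export
extract_length_histograms <- function(bam, markers = msi_panel(), sample_id,
                                      tissue = c("tumor", "normal"),
                                      min_mapq = 1, drop_duplicates = TRUE) {
  tissue <- match.arg(tissue)
  if (!file.exists(bam)) {
    abort(paste0("BAM file not found: ", bam), class = "msipeaks_io_error")
  }
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    abort(paste0("BAM index (.bai) not found for: ", bam),
          class = "msipeaks_io_error")
  }
  header_seqs <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
  absent <- !(markers$chrom %in% header_seqs)
  if (any(absent)) {
    abort(paste0("chromosome '", markers$chrom[which(absent)[1]],
                 "' of marker '", markers$name[which(absent)[1]],
                 "' absent from BAM header"), class = "msipeaks_validation_error")
  }

  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isDuplicate = if (drop_duplicates) FALSE else NA
  )

  rows <- purrr::map(seq_len(nrow(markers)), function(i) {
    m <- markers[i, ]
    param <- Rsamtools::ScanBamParam(
      which = marker_fetch_range(m),
      what = c("seq", "mapq"),
      flag = flag
    )
    res <- Rsamtools::scanBam(bam, param = param)[[1]]
    if (length(res$seq) == 0) return(NULL)
    keep <- !is.na(res$mapq) & res$mapq >= min_mapq
    if (!any(keep)) return(NULL)
    lens <- match_anchor(as.character(res$seq)[keep], m)
    lens <- lens[!is.na(lens) & lens >= 1L]
    if (length(lens) == 0) return(NULL)
    tab <- table(lens)
    tibble(
      sample_id = sample_id, tissue = tissue, marker = m$name,
      repeat_length = as.integer(names(tab)), count = as.integer(tab)
    )
  })
  out <- list_rbind(rows)
  if (nrow(out) == 0) {
    out <- tibble(sample_id = character(), tissue = character(),
                  marker = character(), repeat_length = integer(),
                  count = integer())
  }
  arrange(out, factor(.data$marker, levels = markers$name), .data$repeat_length)
}

# Single point of coordinate conversion: marker coordinates are 1-based
# inclusive, which is also GRanges convention, so no arithmetic is needed here
# beyond constructing the range.
marker_fetch_range <- function(marker) {
  GenomicRanges::GRanges(marker$chrom,
                         IRanges::IRanges(marker$start, marker$end))
}

#' Write or read a depth file
#'
#' The depth file is the tab-separated intermediate between alignment and peak
#' calling: columns `sample_id`, `tissue`, `marker`, `repeat_length`, `count`,
#' preceded by a single `#`-prefixed header line carrying the tool version.
#' `read_depth_file(write_depth_file(x, path))` is the identity.
#'
#' @param depth A depth table as produced by [extract_length_histograms()].
#' @param path Output (or input) file path.
#' @return `write_depth_file()` returns `path` invisibly; `read_depth_file()`
#'   returns the depth tibble.
#' @export
write_depth_file <- function(depth, path) {
  check_depth(depth)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# msipeaks depth file v",
                    as.character(packageVersion("msipeaks"))), con)
  writeLines(paste(c("sample_id", "tissue", "marker", "repeat_length", "count"),
                   collapse = "\t"), con)
  if (nrow(depth) > 0) {
    writeLines(paste(depth$sample_id, depth$tissue, depth$marker,
                     depth$repeat_length, depth$count, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_depth_file
#' @export
read_depth_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("depth file not found: ", path), class = "msipeaks_io_error")
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0 ||
      !identical(strsplit(lines[1], "\t")[[1]],
                 c("sample_id", "tissue", "marker", "repeat_length", "count"))) {
    abort(paste0("malformed depth file header: ", path),
          class = "msipeaks_parse_error")
  }
  body <- lines[-1]
  if (length(body) == 0) {
    return(tibble(sample_id = character(), tissue = character(),
                  marker = character(), repeat_length = integer(),
                  count = integer()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5)) {
    abort(paste0("malformed depth file line ", which(nf != 5)[1] + 1, " in ", path),
          class = "msipeaks_parse_error")
  }
  mat <- do.call(rbind, fields)
  lens <- suppressWarnings(as.integer(mat[, 4]))
  cnts <- suppressWarnings(as.integer(mat[, 5]))
  bad <- which(is.na(lens) | is.na(cnts))
  if (length(bad) > 0) {
    abort(paste0("non-integer length/count at depth file line ", bad[1] + 1,
                 " in ", path), class = "msipeaks_parse_error")
  }
  tibble(sample_id = mat[, 1], tissue = mat[, 2], marker = mat[, 3],
         repeat_length = lens, count = cnts)
}

check_depth <- function(depth) {
  required <- c("sample_id", "tissue", "marker", "repeat_length", "count")
  missing <- setdiff(required, names(depth))
  if (length(missing) > 0) {
    abort(paste0("depth table missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "msipeaks_validation_error")
  }
  if (any(depth$count < 0) || any(depth$repeat_length < 1)) {
    abort("depth table must have count >= 0 and repeat_length >= 1",
          class = "msipeaks_validation_error")
  }
  invisible(depth)
}
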