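# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own implementation paths.

# Character-scanning anchor oracle: locate every occurrence of flank5 by
# substring search, count the repeat-base run after it one character at a
# time, and require flank3 immediately after the run. Leftmost success wins.
oracle_match_anchor <- function(read, flank5, base, flank3) {
  n <- nchar(read)
  start <- 1L
  repeat {
    hit <- regexpr(flank5, substr(read, start, n), fixed = TRUE)
    if (hit == -1L) return(NA_integer_)
    pos <- start + as.integer(hit) - 1L
    i <- pos + nchar(flank5)
    run <- 0L
    while (i + run <= n && substr(read, i + run, i + run) == base) run <- run + 1L
    after <- substr(read, i + run, i + run + nchar(flank3) - 1L)
    if (run >= 1L && identical(after, flank3)) return(run)
    start <- pos + 1L
  }
}

# Try forward then CR, like the implementation's contract.
oracle_match_marker <- function(read, marker) {
  fwd <- oracle_match_anchor(read, marker$flank5, marker$repeat_base,
                             marker$flank3)
  if (!is.na(fwd)) return(fwd)
  oracle_match_anchor(read, marker$flank5_rc, marker$repeat_base_rc,
                      marker$flank3_rc)
}

# Brute-force local-maximum/plateau enumerator: for every index, walk the
# maximal plateau containing it and check both flanks; report each plateau's
# center bin (left-of-middle for even widths).
oracle_peaks <- function(h) {
  n <- length(h)
  idx <- integer(0)
  for (i in seq_len(n)) {
    if (i > 1 && h[i] == h[i - 1]) next  # not the leftmost of its plateau
    j <- i
    while (j < n && h[j + 1] == h[i]) j <- j + 1L
    if (i > 1 && j < n && h[i - 1] < h[i] && h[j + 1] < h[i]) {
      idx <- c(idx, as.integer(i + (j - i) %/% 2))
    }
  }
  idx
}

revcomp_chr <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, NULL), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}

random_histogram <- function(max_bins = 12, max_count = 50) {
  n <- sample.int(max_bins, 1)
  lengths <- sort(sample(5:60, n))
  tibble::tibble(sample_id = "r", tissue = "tumor", marker = "m",
                 repeat_length = lengths,
                 count = sample.int(max_count, n, replace = TRUE))
}

# Peak-set tibbles with the attributes find_peaks() attaches, for direct
# compare_marker() construction in decision-rule tests.
manual_peakset <- function(positions, marker = "Bat25", total_reads = 1000,
                           tissue = "tumor") {
  rows <- tibble::tibble(
    sample_id = "manual", tissue = tissue, marker = marker,
    position = as.integer(sort(positions)),
    height = 100, relative_height = 1
  )
  structure(rows, class = c("msi_peaks", class(tibble::tibble())),
            hyperparameters = hyperparameters(), total_reads = total_reads,
            ids = list(sample_id = "manual", tissue = tissue, marker = marker))
}

marker_call <- function(status, marker = paste0("m", seq_along(status))) {
  tibble::tibble(marker = marker, status = status,
                 tumor_peak_count = 1L, normal_peak_count = 1L,
                 max_position_gap = NA_integer_, reason = "fixture")
}
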