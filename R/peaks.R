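#' Peak-discovery hyperparameters
#'
#' The caller has two tunable hyperparameters: whether to smooth the
#' repeat-length histogram with a window-3 moving average, and the
#' relative-height threshold `r_h` below which a detected peak is discarded as
#' technical noise. `denominator_mode` selects how a peak's relative height is
#' normalized: `"mean_nonzero_bins"` (default) divides by the mean height over
#' nonzero bins of the series, so thresholds above 1 are meaningful across the
#' tuning grid 0.1-3.0; `"peak_sum"` divides by the summed heights of the
#' detected candidate peaks, which caps relative heights at 1.
#'
#' @param smoothing Apply window-3 smoothing before detection (default `TRUE`).
#' @param r_h Relative-height threshold, dimensionless, > 0 (default 0.2).
#' @param denominator_mode `"mean_nonzero_bins"` or `"peak_sum"`.
#' @return A list of class `msi_hyperparameters`.
#' @export
hyperparameters <- function(smoothing = TRUE, r_h = 0.2,
                            denominator_mode = c("mean_nonzero_bins", "peak_sum")) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(is.logical(smoothing), length(smoothing) == 1,
            is.numeric(r_h), length(r_h) == 1, r_h > 0)
  structure(list(smoothing = smoothing, r_h = r_h,
                 denominator_mode = denominator_mode),
            class = "msi_hyperparameters")
}

#' @export
print.msi_hyperparameters <- function(x, ...) {
  cat("MSI peak-discovery hyperparameters\n",
      "  smoothing:        ", x$smoothing, "\n",
      "  r_h threshold:    ", x$r_h, "\n",
      "  rh denominator:   ", x$denominator_mode, "\n", sep = "")
  invisible(x)
}

#' Densify a histogram and pad it with zeros
#'
#' Expands the sparse length->count map to a contiguous series over
#' `[min length - 1, max length + 1]`, filling unobserved lengths with zero.
#' The flanking zeros guarantee that alleles at the ends of the observed range
#' can still be detected as local maxima.
#'
#' @param histogram Tibble with columns `repeat_length` and `count` for one
#'   sample x marker.
#' @return A list with `heights` (numeric vector) and `offset` (the repeat
#'   length of `heights[1]`); an empty histogram yields empty heights and
#'   `NA` offset.
#' @export
pad_and_densify <- function(histogram) {
  if (nrow(histogram) == 0) {
    return(list(heights = numeric(0), offset = NA_integer_))
  }
  lo <- min(histogram$repeat_length) - 1L
  hi <- max(histogram$repeat_length) + 1L
  heights <- numeric(hi - lo + 1L)
  heights[histogram$repeat_length - lo + 1L] <-
    heights[histogram$repeat_length - lo + 1L] + histogram$count
  list(heights = heights, offset = lo)
}

#' Window-3 moving-average smoothing
#'
#' Replaces each height with the mean of itself and its two neighbors,
#' `h_n = (h_{n-1} + h_n + h_{n+1}) / 3`, treating bins outside the series as
#' true zeros. The output range extends one bin on each side so no mass leaks:
#' the histogram total is conserved.
#'
#' @param series A `list(heights, offset)` as returned by [pad_and_densify()].
#' @return A series of the same form, one bin wider on each side.
#' @export
smooth_series <- function(series) {
  h <- series$heights
  if (length(h) == 0) return(series)
  padded <- c(0, 0, h, 0, 0)
  n <- length(padded)
  out <- (padded[1:(n - 2)] + padded[2:(n - 1)] + padded[3:n]) / 3
  list(heights = out, offset = series$offset - 1L)
}

#' Detect candidate peaks as strict local maxima
#'
#' A position is a candidate peak when it is strictly greater than both
#' immediate neighbors ("the eminent number in the middle of three"). A
#' maximal plateau of equal values flanked by strictly lower values on both
#' sides counts as a single candidate at its center bin (the left of the two
#' middle bins for even widths). The center convention keeps a single-length
#' allele at its true position: a lone spike smooths to a width-3 plateau,
#' whose center is the original bin.
#'
#' @param series A zero-padded `list(heights, offset)`.
#' @return Tibble with columns `index` (1-based into `heights`), `position`
#'   (repeat length) and `height`.
#' @export
detect_candidate_peaks <- function(series) {
  h <- series$heights
  empty <- tibble(index = integer(), position = integer(), height = numeric())
  n <- length(h)
  if (n < 3) return(empty)
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && h[j + 1L] == h[i]) j <- j + 1L  # maximal plateau [i, j]
    if (h[i - 1L] < h[i] && j < n && h[j + 1L] < h[i]) {
      idx <- c(idx, i + (j - i) %/% 2L)
    }
    i <- j + 1L
  }
  tibble(index = idx,
         position = idx + series$offset - 1L,
         height = h[idx])
}

#' Annotate candidate peaks with relative heights
#'
#' Under the default `"mean_nonzero_bins"` mode, a peak's relative height is
#' its height divided by the mean height over the nonzero bins of the current
#' series (the series the candidates were detected in, i.e. the smoothed one
#' when smoothing is on). Under `"peak_sum"` it is divided by the sum of all
#' candidate heights.
#'
#' @param candidates Tibble from [detect_candidate_peaks()].
#' @param series The series the candidates were detected in.
#' @param denominator_mode See [hyperparameters()].
#' @return `candidates` with an added `relative_height` column.
#' @export
relative_heights <- function(candidates, series,
                             denominator_mode = c("mean_nonzero_bins", "peak_sum")) {
  denominator_mode <- match.arg(denominator_mode)
  nz <- series$heights[series$heights > 0]
  if (length(nz) == 0) {
    abort("cannot compute relative heights: series has no depth",
          class = "msipeaks_validation_error")
  }
  denom <- switch(denominator_mode,
    mean_nonzero_bins = mean(nz),
    peak_sum = sum(candidates$height)
  )
  mutate(candidates, relative_height = .data$height / denom)
}

#' Discover filtered allele peaks in a repeat-length histogram
#'
#' Composes the full per-marker peak pipeline: zero padding and
#' densification, optional window-3 smoothing, strict local-maximum detection,
#' relative-height annotation, and retention of peaks with
#' `relative_height >= r_h` (compared with a 1e-9 tolerance so grid-value
#' thresholds do not flap on float rounding).
#'
#' @param histogram Tibble with columns `repeat_length`, `count` (and
#'   optionally `sample_id`, `tissue`, `marker`, carried through) for one
#'   sample x marker.
#' @param hp An [hyperparameters()] object.
#' @return A tibble of class `msi_peaks` with columns `sample_id`, `tissue`,
#'   `marker`, `position`, `height`, `relative_height`, ordered by ascending
#'   position; attributes `hyperparameters` and `total_reads` (sum of the
#'   input counts). An empty histogram yields an empty peak set.
#' @examples
#' h <- tibble::tibble(repeat_length = c(24, 25, 26), count = c(20, 100, 10))
#' find_peaks(h, hyperparameters())
#' @export
find_peaks <- function(histogram, hp = hyperparameters()) {
  stopifnot(inherits(hp, "msi_hyperparameters"))
  ids <- list(
    sample_id = histogram$sample_id[1] %||% NA_character_,
    tissue = histogram$tissue[1] %||% NA_character_,
    marker = histogram$marker[1] %||% NA_character_
  )
  total <- sum(histogram$count)
  series <- pad_and_densify(histogram)
  if (length(series$heights) == 0) {
    return(new_msi_peaks(empty_peak_rows(ids), hp, total, ids))
  }
  if (hp$smoothing) series <- smooth_series(series)
  cand <- detect_candidate_peaks(series)
  if (nrow(cand) == 0) {
    return(new_msi_peaks(empty_peak_rows(ids), hp, total, ids))
  }
  cand <- relative_heights(cand, series, hp$denominator_mode)
  kept <- filter(cand, .data$relative_height >= hp$r_h - 1e-9)
  rows <- tibble(
    sample_id = ids$sample_id, tissue = ids$tissue, marker = ids$marker,
    position = kept$position, height = kept$height,
    relative_height = kept$relative_height
  )
  new_msi_peaks(arrange(rows, .data$position), hp, total, ids)
}

#' Discover peaks for every sample x tissue x marker group of a depth table
#'
#' @param depth A depth table (see [extract_length_histograms()]).
#' @param hp An [hyperparameters()] object.
#' @return Tibble with columns `sample_id`, `tissue`, `marker`, `position`,
#'   `height`, `relative_height`, `total_reads`; one row per retained peak.
#'   Groups whose every candidate is filtered out contribute no rows.
#' @export
call_peaks <- function(depth, hp = hyperparameters()) {
  check_depth(depth)
  groups <- group_split(group_by(depth, .data$sample_id, .data$tissue, .data$marker))
  rows <- purrr::map(groups, function(g) {
    ps <- find_peaks(g, hp)
    mutate(as_tibble(ps), total_reads = attr(ps, "total_reads"))
  })
  out <- list_rbind(rows)
  if (nrow(out) == 0) {
    out <- tibble(sample_id = character(), tissue = character(),
                  marker = character(), position = integer(),
                  height = numeric(), relative_height = numeric(),
                  total_reads = integer())
  }
  out
}

new_msi_peaks <- function(rows, hp, total_reads, ids) {
  structure(rows, class = c("msi_peaks", class(tibble())),
            hyperparameters = hp, total_reads = total_reads, ids = ids)
}

empty_peak_rows <- function(ids) {
  tibble(sample_id = character(0), tissue = character(0), marker = character(0),
         position = integer(0), height = numeric(0),
         relative_height = numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
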