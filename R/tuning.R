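#' Read a PCR truth table
#'
#' PCR fragment-length analysis (capillary electrophoresis) supplies the
#' gold-standard peak count per sample per marker. The file is tab-separated
#' with columns `sample_id`, `tissue`, `marker`, `peak_count`; each
#' (sample, tissue, marker) triple may appear at most once.
#'
#' @param path TSV path.
#' @return Tibble with those four columns.
#' @export
read_pcr_truth <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("PCR truth file not found: ", path), class = "msipeaks_io_error")
  }
  truth <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    tissue = readr::col_character(),
    marker = readr::col_character(),
    peak_count = readr::col_integer()
  ))
  check_pcr_truth(truth)
  truth
}

check_pcr_truth <- function(truth) {
  required <- c("sample_id", "tissue", "marker", "peak_count")
  missing <- setdiff(required, names(truth))
  if (length(missing) > 0) {
    abort(paste0("PCR truth missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "msipeaks_parse_error")
  }
  if (nrow(truth) == 0) {
    abort("PCR truth table is empty", class = "msipeaks_validation_error")
  }
  dup <- duplicated(truth[, c("sample_id", "tissue", "marker")])
  if (any(dup)) {
    abort(paste0("duplicate PCR truth entry for (",
                 truth$sample_id[dup][1], ", ", truth$tissue[dup][1], ", ",
                 truth$marker[dup][1], ")"), class = "msipeaks_validation_error")
  }
  if (any(truth$peak_count < 1)) {
    abort("PCR peak counts must be >= 1", class = "msipeaks_validation_error")
  }
  invisible(truth)
}

#' Average absolute peak-count difference against PCR truth
#'
#' The tuning loss: `diff = sum_i sum_t |P_NGS(i,t) - P_PCR(i,t)| / S`, where
#' the outer sum runs over the sample units `i` present in the truth table,
#' the inner over its markers `t`, and `S` is the number of distinct
#' `(sample_id, tissue)` units — the divisor is `S`, not `S x T`, so the loss
#' reads as the average per-sample total peak-count discrepancy.
#'
#' @param ngs_counts Tibble with columns `sample_id`, `tissue`, `marker`,
#'   `peak_count`: the algorithm's peak counts.
#' @param pcr PCR truth tibble (see [read_pcr_truth()]); every truth entry
#'   must be present in `ngs_counts`.
#' @return A non-negative number; 0 iff every count matches.
#' @examples
#' pcr <- tibble::tibble(sample_id = c("s1", "s2"), tissue = "tumor",
#'                       marker = "Bat25", peak_count = c(2L, 1L))
#' ngs <- dplyr::mutate(pcr, peak_count = c(2L, 2L))
#' diff_loss(ngs, pcr) # 0.5
#' @export
diff_loss <- function(ngs_counts, pcr) {
  check_pcr_truth(pcr)
  joined <- left_join(pcr, ngs_counts,
                      by = c("sample_id", "tissue", "marker"),
                      suffix = c("_pcr", "_ngs"))
  miss <- filter(joined, is.na(.data$peak_count_ngs))
  if (nrow(miss) > 0) {
    keys <- paste0("(", miss$sample_id, ", ", miss$tissue, ", ", miss$marker,
                   ")")
    abort(paste0("NGS peak counts missing for: ",
                 paste(utils::head(keys, 5), collapse = ", "),
                 if (length(keys) > 5) " ..." else ""),
          class = "msipeaks_validation_error")
  }
  s <- nrow(distinct(pcr, .data$sample_id, .data$tissue))
  sum(abs(joined$peak_count_ngs - joined$peak_count_pcr)) / s
}

#' Count retained peaks per sample x tissue x marker
#'
#' Convenience wrapper around [call_peaks()]: the peak-count table the tuner
#' compares against PCR truth. Histogram groups whose peaks are all filtered
#' out (or that are absent from `depth`) are reported with `peak_count` 0 when
#' listed in `expect`.
#'
#' @param depth Depth table.
#' @param hp [hyperparameters()].
#' @param expect Optional tibble of (`sample_id`, `tissue`, `marker`) keys
#'   that must appear in the output even with zero retained peaks.
#' @return Tibble `sample_id`, `tissue`, `marker`, `peak_count`.
#' @export
count_peaks <- function(depth, hp = hyperparameters(), expect = NULL) {
  peaks <- call_peaks(depth, hp)
  counts <- summarise(group_by(peaks, .data$sample_id, .data$tissue, .data$marker),
                      peak_count = dplyr::n(), .groups = "drop")
  keys <- distinct(depth, .data$sample_id, .data$tissue, .data$marker)
  if (!is.null(expect)) {
    keys <- distinct(bind_rows(keys, expect[, c("sample_id", "tissue", "marker")]))
  }
  out <- left_join(keys, counts, by = c("sample_id", "tissue", "marker"))
  mutate(out, peak_count = as.integer(tidyr::replace_na(.data$peak_count, 0L)))
}

#' Grid search for the peak-discovery hyperparameters
#'
#' Evaluates [find_peaks()] on every training histogram under every
#' combination of smoothing option and relative-height threshold, scores each
#' combination with [diff_loss()] against PCR truth, and returns the full grid
#' with the optimum. Ties are broken toward smoothing on, then toward the
#' lowest threshold (a lower threshold keeps more sensitivity).
#'
#' @param depth Training depth table (tumor and/or normal histograms).
#' @param pcr PCR truth tibble; its `(sample_id, tissue)` units define which
#'   histograms are scored.
#' @param thresholds Candidate `r_h` values (default `0.1, 0.2, ..., 3.0`).
#' @param smoothing_options Candidate smoothing settings (default both).
#' @param denominator_mode Passed to [hyperparameters()].
#' @param tissues Tissues to score (default both); pass `"tumor"` to train on
#'   tumor histograms only.
#' @return An object of class `msi_tuning`: list with `grid` (tibble
#'   `smoothing`, `r_h`, `diff`), `best` (an [hyperparameters()] object) and
#'   `best_diff`.
#' @export
grid_search <- function(depth, pcr,
                        thresholds = seq(0.1, 3.0, by = 0.1),
                        smoothing_options = c(TRUE, FALSE),
                        denominator_mode = "mean_nonzero_bins",
                        tissues = c("tumor", "normal")) {
  if (length(thresholds) == 0) {
    abort("thresholds must be non-empty", class = "msipeaks_validation_error")
  }
  check_depth(depth)
  check_pcr_truth(pcr)
  pcr <- filter(pcr, .data$tissue %in% tissues)
  if (nrow(pcr) == 0) {
    abort("PCR truth has no entries for the requested tissues",
          class = "msipeaks_validation_error")
  }
  depth <- filter(depth, .data$tissue %in% tissues)
  if (nrow(depth) == 0) {
    abort("training depth table is empty for the requested tissues",
          class = "msipeaks_validation_error")
  }

  combos <- tidyr::expand_grid(smoothing = smoothing_options, r_h = thresholds)
  diffs <- purrr::map2_dbl(combos$smoothing, combos$r_h, function(sm, th) {
    hp <- hyperparameters(smoothing = sm, r_h = th,
                          denominator_mode = denominator_mode)
    counts <- count_peaks(depth, hp, expect = pcr)
    diff_loss(counts, pcr)
  })
  grid <- mutate(combos, diff = diffs)

  ranked <- arrange(grid, .data$diff, dplyr::desc(.data$smoothing), .data$r_h)
  best <- ranked[1, ]
  structure(list(
    grid = grid,
    best = hyperparameters(smoothing = best$smoothing, r_h = best$r_h,
                           denominator_mode = denominator_mode),
    best_diff = best$diff
  ), class = "msi_tuning")
}

#' @export
print.msi_tuning <- function(x, ...) {
  cat("MSI hyperparameter grid search (", nrow(x$grid), " combinations)\n",
      "  best: smoothing=", x$best$smoothing, ", r_h=", x$best$r_h,
      "  (diff = ", format(x$best_diff, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @describeIn grid_search The full grid as a tibble.
#' @param x An `msi_tuning` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.msi_tuning <- function(x, ...) x$grid

#' @describeIn grid_search One-row summary of the optimum.
#' @exportS3Method generics::glance
glance.msi_tuning <- function(x, ...) {
  tibble(smoothing = x$best$smoothing, r_h = x$best$r_h,
         best_diff = x$best_diff, n_combinations = nrow(x$grid))
}

#' Write a tuning report TSV (`smoothing`, `threshold`, `diff`)
#' @param result An `msi_tuning` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tuning_report <- function(result, path) {
  stopifnot(inherits(result, "msi_tuning"))
  readr::write_tsv(
    tibble(smoothing = result$grid$smoothing,
           threshold = result$grid$r_h, diff = result$grid$diff),
    path)
  invisible(path)
}
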