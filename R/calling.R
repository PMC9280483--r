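#' Compare tumor and normal peak sets for one marker
#'
#' A marker is unstable when the tumor and normal peak counts differ, or, when
#' the counts are equal, when peaks paired in ascending-position order are
#' separated by a maximum absolute gap of two or more repeat units. A marker
#' where either sample has fewer than `min_reads` anchor-matched reads is
#' reported `uninformative` and excluded from patient classification.
#'
#' @param tumor,normal `msi_peaks` objects from [find_peaks()] for the same
#'   marker, produced with identical hyperparameters.
#' @param min_reads Minimum anchor-matched reads per sample (default 20).
#' @param tumor_reads,normal_reads Override the matched-read totals carried on
#'   the peak sets (used when peaks come from a plain tibble).
#' @return One-row tibble: `marker`, `status` (`stable` / `unstable` /
#'   `uninformative`), `tumor_peak_count`, `normal_peak_count`,
#'   `max_position_gap` (NA unless counts are equal and both positive),
#'   `reason`.
#' @examples
#' hp <- hyperparameters()
#' t <- find_peaks(tibble::tibble(marker = "Bat25",
#'   repeat_length = c(18, 25), count = c(60, 60)), hp)
#' n <- find_peaks(tibble::tibble(marker = "Bat25",
#'   repeat_length = 25, count = 120), hp)
#' compare_marker(t, n)$status # "unstable"
#' @export
compare_marker <- function(tumor, normal, min_reads = 20,
                           tumor_reads = NULL, normal_reads = NULL) {
  t_marker <- peak_marker(tumor)
  n_marker <- peak_marker(normal)
  if (!is.na(t_marker) && !is.na(n_marker) && !identical(t_marker, n_marker)) {
    abort(paste0("marker mismatch: tumor '", t_marker, "' vs normal '",
                 n_marker, "'"), class = "msipeaks_validation_error")
  }
  marker <- if (!is.na(t_marker)) t_marker else n_marker
  t_total <- tumor_reads %||% attr(tumor, "total_reads") %||% NA_integer_
  n_total <- normal_reads %||% attr(normal, "total_reads") %||% NA_integer_

  if ((!is.na(t_total) && t_total < min_reads) ||
      (!is.na(n_total) && n_total < min_reads)) {
    return(marker_call_row(marker, "uninformative", nrow(tumor), nrow(normal),
                           NA_integer_,
                           sprintf("matched reads below %d (tumor %s, normal %s)",
                                   min_reads, t_total, n_total)))
  }

  np_t <- nrow(tumor)
  np_n <- nrow(normal)
  if (np_t != np_n) {
    return(marker_call_row(marker, "unstable", np_t, np_n, NA_integer_,
                           sprintf("peak counts differ (tumor %d vs normal %d)",
                                   np_t, np_n)))
  }
  if (np_t == 0) {
    return(marker_call_row(marker, "stable", 0L, 0L, NA_integer_,
                           "no peaks in either sample"))
  }
  gap <- max(abs(sort(tumor$position) - sort(normal$position)))
  status <- if (gap >= 2) "unstable" else "stable"
  marker_call_row(marker, status, np_t, np_n, as.integer(gap),
                  sprintf("equal peak counts (%d); max position gap %d", np_t, gap))
}

marker_call_row <- function(marker, status, np_t, np_n, gap, reason) {
  tibble(marker = marker, status = status,
         tumor_peak_count = as.integer(np_t),
         normal_peak_count = as.integer(np_n),
         max_position_gap = gap, reason = reason)
}

peak_marker <- function(peaks) {
  if (nrow(peaks) > 0 && "marker" %in% names(peaks)) return(peaks$marker[1])
  ids <- attr(peaks, "ids")
  if (!is.null(ids)) return(ids$marker)
  NA_character_
}

#' Classify a patient from their panel of marker calls
#'
#' Counts unstable markers among the informative ones: two or more unstable
#' markers give MSI-H, otherwise MSI-L (the binary scheme that merges MSS into
#' MSI-L). Uninformative markers are excluded from the count but reported.
#'
#' @param marker_calls Tibble of rows from [compare_marker()], one patient.
#' @param sample_id Patient identifier.
#' @return An object of class `msi_patient_call`: a list with `sample_id`,
#'   `status` (`"MSI-H"` / `"MSI-L"`), `n_unstable`, `n_evaluated`,
#'   `unstable_markers` and the `marker_calls` tibble.
#' @export
classify_patient <- function(marker_calls, sample_id) {
  informative <- filter(marker_calls, .data$status != "uninformative")
  if (nrow(informative) == 0) {
    abort(paste0("patient '", sample_id,
                 "' is uncallable: no informative markers"),
          class = "msipeaks_uncallable_error")
  }
  unstable <- filter(informative, .data$status == "unstable")
  n_unstable <- nrow(unstable)
  structure(list(
    sample_id = sample_id,
    status = if (n_unstable >= 2) "MSI-H" else "MSI-L",
    n_unstable = n_unstable,
    n_evaluated = nrow(informative),
    unstable_markers = unstable$marker,
    marker_calls = marker_calls
  ), class = "msi_patient_call")
}

#' End-to-end MSI call for one tumor/normal pair
#'
#' Runs the whole pipeline: histogram extraction from both BAMs (or directly
#' from depth tables), peak discovery under `hp` at every marker, per-marker
#' stable/unstable comparison, and patient classification. Deterministic for
#' fixed inputs.
#'
#' @param tumor,normal Indexed BAM paths, or depth tables (tibbles with
#'   columns `sample_id`, `tissue`, `marker`, `repeat_length`, `count`) as
#'   written by [extract_length_histograms()] — the two input forms give
#'   identical results.
#' @param markers Marker panel tibble (default: bundled six-marker panel).
#' @param hp Peak-discovery [hyperparameters()].
#' @param min_reads Per-marker depth floor passed to [compare_marker()].
#' @param min_mapq,drop_duplicates Passed to [extract_length_histograms()]
#'   when the inputs are BAMs.
#' @param sample_id Patient identifier (default: derived from the tumor input).
#' @return An `msi_patient_call` object; see [classify_patient()].
#' @export
call_sample_pair <- function(tumor, normal, markers = msi_panel(),
                             hp = hyperparameters(), min_reads = 20,
                             min_mapq = 1, drop_duplicates = TRUE,
                             sample_id = NULL) {
  as_depth <- function(x, tissue, id) {
    if (is.character(x) && length(x) == 1) {
      extract_length_histograms(x, markers, sample_id = id, tissue = tissue,
                                min_mapq = min_mapq,
                                drop_duplicates = drop_duplicates)
    } else {
      check_depth(x)
      x
    }
  }
  if (is.null(sample_id)) {
    sample_id <- if (is.character(tumor) && length(tumor) == 1) {
      sub("\\.bam$", "", basename(tumor))
    } else if (nrow(tumor) > 0) tumor$sample_id[1] else "sample"
  }
  tumor_depth <- as_depth(tumor, "tumor", sample_id)
  normal_depth <- as_depth(normal, "normal", sample_id)

  calls <- purrr::map(markers$name, function(mk) {
    th <- filter(tumor_depth, .data$marker == mk)
    nh <- filter(normal_depth, .data$marker == mk)
    tp <- find_peaks(mutate(th, marker = mk), hp)
    np <- find_peaks(mutate(nh, marker = mk), hp)
    compare_marker(tp, np, min_reads = min_reads)
  }) |> list_rbind()
  calls$marker <- markers$name  # stable panel order, even for empty histograms
  classify_patient(calls, sample_id)
}

#' @export
print.msi_patient_call <- function(x, ...) {
  cat("MSI patient call: ", x$sample_id, "\n",
      "  status:      ", x$status, "\n",
      "  unstable:    ", x$n_unstable, " of ", x$n_evaluated,
      " informative markers\n", sep = "")
  if (length(x$unstable_markers) > 0) {
    cat("  markers:     ", paste(x$unstable_markers, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @describeIn classify_patient Per-marker evidence as a tibble.
#' @param x An `msi_patient_call`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.msi_patient_call <- function(x, ...) {
  mutate(x$marker_calls, sample_id = x$sample_id, .before = 1)
}

#' @describeIn classify_patient One-row patient summary.
#' @exportS3Method generics::glance
glance.msi_patient_call <- function(x, ...) {
  tibble(sample_id = x$sample_id, status = x$status,
         n_unstable = x$n_unstable, n_evaluated = x$n_evaluated,
         unstable_markers = paste(x$unstable_markers, collapse = ","))
}

#' Write a patient call report
#'
#' Writes the full evidence as JSON and/or a one-line TSV summary
#' (`sample_id`, `status`, `n_unstable`, `unstable_marker_names`).
#'
#' @param call An `msi_patient_call`.
#' @param json Path for the JSON report, or `NULL` to skip.
#' @param tsv Path for the TSV summary, or `NULL` to skip.
#' @return `call`, invisibly.
#' @export
write_msi_report <- function(call, json = NULL, tsv = NULL) {
  stopifnot(inherits(call, "msi_patient_call"))
  if (!is.null(json)) {
    payload <- list(
      sample_id = call$sample_id, status = call$status,
      n_unstable = call$n_unstable, n_evaluated = call$n_evaluated,
      unstable_markers = call$unstable_markers,
      marker_calls = call$marker_calls
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv)) {
    line <- paste(call$sample_id, call$status, call$n_unstable,
                  paste(call$unstable_markers, collapse = ","), sep = "\t")
    writeLines(c("sample_id\tstatus\tn_unstable\tunstable_marker_names", line),
               tsv)
  }
  invisible(call)
}
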