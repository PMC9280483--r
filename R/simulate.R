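#' Allele model for histogram simulation
#'
#' Describes one allele at one marker: its true (modal) repeat length, its
#' expected read depth, and the noise processes that broaden the observed
#' length distribution. Stutter is modeled as a geometrically decaying shift,
#' mostly downward (the classic PCR slippage signature): a read's observed
#' length is `modal - d + u` with `d ~ Geom(1 - stutter_down_rate)` and
#' `u ~ Geom(1 - stutter_up_rate)`. Each read is independently replaced, with
#' probability `noise_rate`, by a stray read of uniform length within 15 units
#' of the modal length — the isolated one-read spikes that smoothing and the
#' relative-height threshold exist to remove.
#'
#' @param modal_length True allele repeat length (bp).
#' @param depth Expected read count (Poisson mean).
#' @param stutter_down_rate,stutter_up_rate Geometric decay parameters in
#'   `[0, 1)`; defaults 0.10 down, 0.05 up. The down bias mimics PCR
#'   slippage; the rates are kept small enough that the smoothed mode stays at
#'   the true allele length (the minus-one shoulder must not rival the modal
#'   bin after window-3 averaging).
#' @param noise_rate Stray-read probability in `[0, 1)`; default 0.01.
#' @return One-row tibble usable (row-bound) as the `alleles` argument of
#'   [simulate_histogram()].
#' @export
allele_model <- function(modal_length, depth, stutter_down_rate = 0.10,
                         stutter_up_rate = 0.05, noise_rate = 0.01) {
  stopifnot(modal_length >= 1, depth > 0,
            stutter_down_rate >= 0, stutter_down_rate < 1,
            stutter_up_rate >= 0, stutter_up_rate < 1,
            noise_rate >= 0, noise_rate < 1)
  tibble(modal_length = as.integer(modal_length), depth = depth,
         stutter_down_rate = stutter_down_rate,
         stutter_up_rate = stutter_up_rate, noise_rate = noise_rate)
}

#' Simulate a stutter-broadened repeat-length histogram
#'
#' Draws a Poisson number of reads per allele, shifts each read's length by
#' the allele's stutter model, and replaces a `noise_rate` fraction with
#' uniform stray lengths. Deterministic for a fixed seed.
#'
#' @param alleles Tibble of [allele_model()] rows.
#' @param seed Integer seed.
#' @param sample_id,tissue,marker Identifiers stamped on the output rows.
#' @return Depth-table tibble (`sample_id`, `tissue`, `marker`,
#'   `repeat_length`, `count`) with attribute `modal_lengths` recording the
#'   ground truth.
#' @export
simulate_histogram <- function(alleles, seed, sample_id = "sim",
                               tissue = "tumor", marker = "marker") {
  stopifnot(nrow(alleles) >= 1)
  lengths <- with_seed(seed, {
    unlist(purrr::map(seq_len(nrow(alleles)), function(i) {
      a <- alleles[i, ]
      n <- rpois(1, a$depth)
      if (n == 0) return(integer(0))
      d <- rgeom(n, prob = 1 - a$stutter_down_rate)
      u <- rgeom(n, prob = 1 - a$stutter_up_rate)
      len <- a$modal_length - d + u
      stray <- runif(n) < a$noise_rate
      if (any(stray)) {
        lo <- max(1L, a$modal_length - 15L)
        len[stray] <- sample(seq(lo, a$modal_length + 15L), sum(stray),
                             replace = TRUE)
      }
      pmax(len, 1L)
    }))
  })
  tab <- table(lengths)
  out <- tibble(sample_id = sample_id, tissue = tissue, marker = marker,
                repeat_length = as.integer(names(tab)),
                count = as.integer(tab))
  attr(out, "modal_lengths") <- sort(unique(alleles$modal_length))
  out
}

#' Simulate a tumor/normal cohort with known MSI truth
#'
#' Every normal sample carries a single allele at each marker's reference
#' repeat length. MSI-H pairs gain a novel shorter tumor allele (4-7 repeat
#' units below the reference, half the depth each) at 2-3 randomly chosen
#' markers; MSI-L pairs at 0-1 markers. Truth labels and the shifted markers
#' are recorded.
#'
#' @param n_pairs Number of tumor/normal pairs.
#' @param fraction_msih Fraction of pairs that are MSI-H (default 0.2).
#' @param seed Integer seed.
#' @param markers Marker panel tibble.
#' @param depth Per-marker expected read depth (default 200).
#' @param stutter_down_rate,stutter_up_rate,noise_rate Noise settings shared
#'   by all alleles; see [allele_model()] for the defaults and their rationale.
#' @return List with `depth` (row-bound depth table for all samples, both
#'   tissues) and `truth` (tibble `sample_id`, `true_status`,
#'   `shifted_markers`).
#' @export
simulate_cohort <- function(n_pairs, fraction_msih = 0.2, seed,
                            markers = msi_panel(), depth = 200,
                            stutter_down_rate = 0.10, stutter_up_rate = 0.05,
                            noise_rate = 0.01) {
  stopifnot(n_pairs >= 0, fraction_msih >= 0, fraction_msih <= 1)
  if (n_pairs == 0) {
    return(list(depth = tibble(sample_id = character(), tissue = character(),
                               marker = character(), repeat_length = integer(),
                               count = integer()),
                truth = tibble(sample_id = character(),
                               true_status = character(),
                               shifted_markers = character())))
  }
  n_msih <- round(n_pairs * fraction_msih)
  plan <- with_seed(seed, {
    status <- sample(c(rep("MSI-H", n_msih), rep("MSI-L", n_pairs - n_msih)))
    purrr::map(seq_len(n_pairs), function(i) {
      n_shift <- if (status[i] == "MSI-H") sample(2:3, 1) else sample(0:1, 1)
      shifted <- if (n_shift > 0) sample(markers$name, n_shift) else character(0)
      shifts <- if (n_shift > 0) sample(4:7, n_shift, replace = TRUE) else integer(0)
      seeds <- sample.int(2^30, nrow(markers) * 2)
      list(status = status[i], shifted = shifted, shifts = shifts,
           seeds = seeds)
    })
  })

  rows <- purrr::map(seq_len(n_pairs), function(i) {
    p <- plan[[i]]
    id <- sprintf("sim%03d", i)
    per_marker <- purrr::map(seq_len(nrow(markers)), function(j) {
      mk <- markers[j, ]
      germline <- allele_model(mk$ref_repeat_length, depth,
                               stutter_down_rate, stutter_up_rate, noise_rate)
      normal <- simulate_histogram(germline, seed = p$seeds[2 * j - 1],
                                   sample_id = id, tissue = "normal",
                                   marker = mk$name)
      tumor_alleles <- if (mk$name %in% p$shifted) {
        shift <- p$shifts[match(mk$name, p$shifted)]
        bind_rows(
          allele_model(mk$ref_repeat_length, depth / 2,
                       stutter_down_rate, stutter_up_rate, noise_rate),
          allele_model(mk$ref_repeat_length - shift, depth / 2,
                       stutter_down_rate, stutter_up_rate, noise_rate)
        )
      } else {
        germline
      }
      tumor <- simulate_histogram(tumor_alleles, seed = p$seeds[2 * j],
                                  sample_id = id, tissue = "tumor",
                                  marker = mk$name)
      bind_rows(tumor, normal)
    })
    list_rbind(per_marker)
  })

  truth <- tibble(
    sample_id = sprintf("sim%03d", seq_len(n_pairs)),
    true_status = purrr::map_chr(plan, "status"),
    shifted_markers = purrr::map_chr(plan, function(p) {
      paste(p$shifted, collapse = ",")
    })
  )
  list(depth = list_rbind(rows), truth = truth)
}

#' Deterministic training set with a planted grid-search optimum
#'
#' Constructs per-marker histograms whose true two-allele peak structure is
#' recovered exactly at (smoothing on, r_h = 0.2) and corrupted at every other
#' grid combination. Each marker carries a dominant allele (triplet
#' `360, 720, 360` centered on the reference length), a minor allele 7 units
#' below it (`20, 40, 20`), and two isolated 40-read noise spikes. Under
#' window-3 smoothing the noise spikes collapse to relative height 2/15
#' (removed at 0.2, kept at 0.1) while the minor allele keeps 4/15 (kept at
#' 0.2, removed at 0.3); without smoothing no threshold on the grid yields two
#' peaks. The matching PCR truth table records two peaks everywhere.
#'
#' @param n_samples Number of identical training samples (default 2).
#' @param markers Marker panel tibble.
#' @param tissue Tissue label for the training histograms (default "tumor").
#' @return List with `depth` (training depth table) and `pcr` (truth tibble
#'   `sample_id`, `tissue`, `marker`, `peak_count`).
#' @export
plant_grid_optimum <- function(n_samples = 2, markers = msi_panel(),
                               tissue = "tumor") {
  stopifnot(n_samples >= 1)
  one_marker <- function(mk) {
    ref <- mk$ref_repeat_length
    tibble(
      marker = mk$name,
      repeat_length = as.integer(c(ref - 11,                  # noise spike
                                   (ref - 8):(ref - 6),       # minor allele
                                   (ref - 1):(ref + 1),       # major allele
                                   ref + 5)),                 # noise spike
      count = c(40L, 20L, 40L, 20L, 360L, 720L, 360L, 40L)
    )
  }
  per_marker <- list_rbind(purrr::map(seq_len(nrow(markers)),
                                      function(j) one_marker(markers[j, ])))
  depth <- list_rbind(purrr::map(seq_len(n_samples), function(i) {
    mutate(per_marker, sample_id = sprintf("train%02d", i), tissue = tissue,
           .before = 1)
  }))
  pcr <- distinct(depth, .data$sample_id, .data$tissue, .data$marker)
  pcr$peak_count <- 2L
  list(depth = depth, pcr = pcr)
}

#' Write a fixture BAM realizing a repeat-length plan
#'
#' Emits a coordinate-sorted, indexed BAM whose reads each embed
#' `flank5 + repeat_base x k + flank3` in neutral padding at the marker's
#' locus, with the multiset of `k` matching `plan`. Running
#' [extract_length_histograms()] on the output reproduces the plan exactly.
#'
#' @param plan Tibble with columns `marker`, `repeat_length`, `count` and
#'   optionally `duplicate` (logical: emit the reads duplicate-flagged).
#' @param markers Marker panel tibble.
#' @param path Output BAM path (`.bam`); the index is written alongside.
#' @return The BAM path, invisibly.
#' @export
write_fixture_bam <- function(plan, markers = msi_panel(), path) {
  stopifnot(endsWith(path, ".bam"))
  if (nrow(plan) > 0) {
    unknown <- setdiff(plan$marker, markers$name)
    if (length(unknown) > 0) {
      abort(paste0("plan references unknown marker(s): ",
                   paste(unknown, collapse = ", ")),
            class = "msipeaks_validation_error")
    }
  }
  if (!"duplicate" %in% names(plan)) plan$duplicate <- FALSE

  chrom_len <- summarise(group_by(tibble(chrom = markers$chrom,
                                         end = markers$end), .data$chrom),
                         len = max(.data$end) + 1000L, .groups = "drop")
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", chrom_len$chrom, "\tLN:", chrom_len$len))

  pad <- "GGATC"
  records <- character(0)
  if (nrow(plan) > 0) {
    expanded <- tidyr::uncount(plan, weights = .data$count, .remove = FALSE)
    records <- purrr::map_chr(seq_len(nrow(expanded)), function(i) {
      row <- expanded[i, ]
      mk <- markers[match(row$marker, markers$name), ]
      seq <- paste0(pad, mk$flank5, strrep(mk$repeat_base, row$repeat_length),
                    mk$flank3, pad)
      flag <- if (isTRUE(row$duplicate)) 1024L else 0L
      paste(sprintf("fx%06d", i), flag, mk$chrom, mk$start, 60L,
            paste0(nchar(seq), "M"), "*", 0L, 0L, seq,
            strrep("I", nchar(seq)), sep = "\t")
    })
  }

  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  writeLines(c(header, records), sam)
  dest <- sub("\\.bam$", "", path)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
  invisible(path)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
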