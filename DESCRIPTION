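Package: msipeaks
Title: Microsatellite Instability Calling from Tumor-Normal Repeat-Length Histograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects microsatellite instability (MSI) from paired tumor/normal
    next-generation sequencing data. Reads overlapping a panel of six
    mononucleotide microsatellite markers are matched against flanking anchor
    sequences to measure repeat-tract lengths, producing per-marker
    repeat-length histograms. Peaks (allele lengths) are discovered by
    zero-padded local-maximum detection with optional window-3 smoothing and a
    relative-height threshold that suppresses PCR-stutter and sequencing noise.
    Markers are called stable or unstable by comparing tumor and normal peak
    sets (different peak counts, or a positional gap of two or more repeat
    units), and a patient is classified MSI-H when two or more markers are
    unstable. Includes a grid-search tuner that minimizes the average absolute
    peak-count difference against PCR fragment-analysis truth, a seeded
    simulator of stutter-broadened allele histograms and synthetic cohorts,
    fixture BAM generation, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Rsamtools,
    GenomicRanges,
    IRanges,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
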