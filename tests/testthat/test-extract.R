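panel <- msi_panel()

test_that("extraction reproduces a fixture BAM's planted length plan", {
  bam <- tempfile(fileext = ".bam")
  plan <- tibble::tibble(marker = "Bat25", repeat_length = 25L, count = 30L)
  write_fixture_bam(plan, panel, bam)
  depth <- extract_length_histograms(bam, panel, sample_id = "fx",
                                     tissue = "tumor")
  expect_equal(depth$marker, "Bat25")
  expect_equal(depth$repeat_length, 25L)
  expect_equal(depth$count, 30L)

  # mixed lengths across several markers, shuffled plan rows: extraction is
  # order-independent and exact
  plan2 <- tibble::tibble(
    marker = c("Bat25", "Bat25", "NR21", "Mono27"),
    repeat_length = c(25L, 18L, 21L, 22L),
    count = c(20L, 10L, 15L, 40L)
  )
  set.seed(5)
  for (perm in 1:3) {
    bam2 <- tempfile(fileext = ".bam")
    write_fixture_bam(plan2[sample.int(4), ], panel, bam2)
    depth2 <- extract_length_histograms(bam2, panel, sample_id = "fx",
                                        tissue = "tumor")
    expect_equal(
      dplyr::arrange(depth2[, c("marker", "repeat_length", "count")],
                     marker, repeat_length),
      dplyr::arrange(plan2, marker, repeat_length)
    )
  }
})

test_that("a region with no matching reads yields no rows, not an error", {
  bam <- tempfile(fileext = ".bam")
  write_fixture_bam(tibble::tibble(marker = "Bat25", repeat_length = 25L,
                                   count = 5L), panel, bam)
  nr21_only <- panel[panel$name == "NR21", ]
  depth <- extract_length_histograms(bam, nr21_only, sample_id = "fx",
                                     tissue = "normal")
  expect_equal(nrow(depth), 0)
})

test_that("duplicate-flagged reads are dropped unless kept explicitly", {
  bam <- tempfile(fileext = ".bam")
  plan <- tibble::tibble(marker = "Bat25", repeat_length = c(25L, 25L),
                         count = c(12L, 8L), duplicate = c(FALSE, TRUE))
  write_fixture_bam(plan, panel, bam)
  dropped <- extract_length_histograms(bam, panel, sample_id = "fx",
                                       tissue = "tumor")
  expect_equal(dropped$count, 12L)
  kept <- extract_length_histograms(bam, panel, sample_id = "fx",
                                    tissue = "tumor", drop_duplicates = FALSE)
  expect_equal(kept$count, 20L)
})

test_that("low-mapq, secondary and unmapped records are filtered out", {
  # hand-written SAM: one good read, one mapq 0, one secondary, one unmapped
  sam <- tempfile(fileext = ".sam")
  bat25 <- panel[1, ]
  seq <- paste0("GGATC", bat25$flank5, strrep("T", 25), bat25$flank3, "GGATC")
  qual <- strrep("I", nchar(seq))
  rec <- function(name, flag, mapq) {
    paste(name, flag, "chr4", bat25$start, mapq, paste0(nchar(seq), "M"),
          "*", 0, 0, seq, qual, sep = "\t")
  }
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:chr4\tLN:55600000",
               rec("good", 0, 60), rec("lowq", 0, 0),
               rec("secondary", 256, 60), rec("unmapped", 4, 0)), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  depth <- extract_length_histograms(bam, bat25, sample_id = "fx",
                                     tissue = "tumor", min_mapq = 1)
  expect_equal(depth$count, 1L)
  # lowering the mapq floor admits the mapq-0 primary read
  depth0 <- extract_length_histograms(bam, bat25, sample_id = "fx",
                                      tissue = "tumor", min_mapq = 0)
  expect_equal(depth0$count, 2L)
})

test_that("missing index and absent chromosomes produce explicit errors", {
  bam <- tempfile(fileext = ".bam")
  write_fixture_bam(tibble::tibble(marker = "Bat25", repeat_length = 25L,
                                   count = 3L), panel, bam)
  file.remove(paste0(bam, ".bai"))
  expect_error(
    extract_length_histograms(bam, panel, sample_id = "x", tissue = "tumor"),
    "index", class = "msipeaks_io_error")

  bat25_only <- panel[1, ]
  bam2 <- tempfile(fileext = ".bam")
  write_fixture_bam(tibble::tibble(marker = "Bat25", repeat_length = 25L,
                                   count = 3L), bat25_only, bam2)
  expect_error(
    extract_length_histograms(bam2, panel, sample_id = "x", tissue = "tumor"),
    "NR21|Bat26|Mono27", class = "msipeaks_validation_error")
})

test_that("histogram totals equal the number of reads the anchor oracle matches", {
  bam <- tempfile(fileext = ".bam")
  set.seed(9)
  plan <- tibble::tibble(
    marker = rep(panel$name, each = 2),
    repeat_length = as.integer(rep(panel$ref_repeat_length, each = 2) +
                                 c(0L, -5L)),
    count = sample(5:25, 12, replace = TRUE)
  )
  write_fixture_bam(plan, panel, bam)
  depth <- extract_length_histograms(bam, panel, sample_id = "fx",
                                     tissue = "tumor")

  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = "seq"))
  reads <- as.character(res[[1]]$seq)
  for (mk in panel$name) {
    m <- panel[panel$name == mk, ]
    oracle_n <- sum(!is.na(vapply(reads, oracle_match_marker,
                                  integer(1), marker = m)))
    expect_equal(sum(depth$count[depth$marker == mk]), oracle_n)
  }
})

test_that("depth files round-trip through write and read", {
  depth <- tibble::tibble(
    sample_id = rep("s1", 4), tissue = c("tumor", "tumor", "normal", "normal"),
    marker = c("Bat25", "Bat25", "Bat25", "NR21"),
    repeat_length = c(18L, 25L, 25L, 21L), count = c(10L, 30L, 40L, 25L)
  )
  path <- tempfile(fileext = ".tsv")
  write_depth_file(depth, path)
  expect_equal(read_depth_file(path), depth)

  # empty table: header-only file reads back empty
  empty <- depth[0, ]
  path2 <- tempfile(fileext = ".tsv")
  write_depth_file(empty, path2)
  expect_equal(nrow(read_depth_file(path2)), 0)

  # a full tumor+normal six-marker set survives with order preserved
  co <- simulate_cohort(1, fraction_msih = 1, seed = 31)
  path3 <- tempfile(fileext = ".tsv")
  write_depth_file(co$depth, path3)
  expect_equal(read_depth_file(path3), co$depth, ignore_attr = TRUE)
})

test_that("malformed depth files fail with the line identified", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# msipeaks depth file v0",
               "sample_id\ttissue\tmarker\trepeat_length\tcount",
               "s1\ttumor\tBat25\t25\t30",
               "s1\ttumor\tBat25\t26"), path)
  expect_error(read_depth_file(path), "line 3",
               class = "msipeaks_parse_error")

  path2 <- tempfile(fileext = ".tsv")
  writeLines("not a depth file", path2)
  expect_error(read_depth_file(path2), "header",
               class = "msipeaks_parse_error")
})
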