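hist1 <- function(lengths, counts) {
  tibble::tibble(sample_id = "s", tissue = "tumor", marker = "m",
                 repeat_length = as.integer(lengths), count = counts)
}

test_that("pad_and_densify fills gaps and adds one flanking zero per side", {
  s <- pad_and_densify(hist1(21, 3))
  expect_equal(s$heights, c(0, 3, 0))
  expect_equal(s$offset, 20L)

  s2 <- pad_and_densify(hist1(c(20, 22), c(1, 5)))
  expect_equal(s2$heights, c(0, 1, 0, 5, 0))
  expect_equal(s2$offset, 19L)

  s3 <- pad_and_densify(hist1(integer(0), integer(0)))
  expect_length(s3$heights, 0)
  expect_true(is.na(s3$offset))
})

test_that("window-3 smoothing spreads mass without losing any", {
  spike <- smooth_series(list(heights = c(0, 6, 0), offset = 20L))
  expect_equal(spike$heights, c(0, 2, 2, 2, 0))
  expect_equal(spike$offset, 19L)

  plateau <- smooth_series(list(heights = c(0, 3, 3, 3, 0), offset = 10L))
  expect_equal(plateau$heights, c(0, 1, 2, 3, 2, 1, 0))

  zeros <- smooth_series(list(heights = rep(0, 4), offset = 1L))
  expect_equal(zeros$heights, rep(0, 6))
})

test_that("smoothing conserves total mass on random histograms", {
  set.seed(303)
  for (i in 1:1000) {
    h <- random_histogram()
    s <- pad_and_densify(h)
    expect_equal(sum(smooth_series(s)$heights), sum(h$count))
  }
})

test_that("candidate detection matches the stated local-maximum examples", {
  peaks_of <- function(h) detect_candidate_peaks(list(heights = h, offset = 1L))

  expect_equal(peaks_of(c(0, 1, 3, 1, 0))$index, 3L)
  # a plateau flanked by strictly lower values is one candidate at its center
  expect_equal(peaks_of(c(0, 5, 5, 5, 0))$index, 3L)
  expect_equal(peaks_of(c(0, 5, 5, 0))$index, 2L)
  two <- peaks_of(c(0, 2, 1, 4, 1, 0))
  expect_equal(two$index, c(2L, 4L))
  expect_equal(two$height, c(2, 4))
  # monotone ramps have no interior maximum
  expect_equal(nrow(peaks_of(c(0, 1, 2, 3, 3, 3))), 0)
})

test_that("candidate detection equals the brute-force enumerator on random series", {
  set.seed(404)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    h <- c(0, sample(0:6, n - 2, replace = TRUE), 0)
    got <- detect_candidate_peaks(list(heights = h, offset = 1L))$index
    expect_identical(got, oracle_peaks(h))
  }
})

test_that("relative heights follow the selected denominator convention", {
  series <- list(heights = c(0, 2, 0, 10, 0, 3, 0), offset = 1L)
  cand <- detect_candidate_peaks(series)
  # nonzero bins 2, 10, 3: mean 5 -> the height-10 candidate has rh 2
  mean_mode <- relative_heights(cand, series, "mean_nonzero_bins")
  expect_equal(mean_mode$relative_height[mean_mode$height == 10], 2)

  # the literal printed formula: heights over the sum of candidate heights
  sum_mode <- relative_heights(cand, series, "peak_sum")
  expect_equal(sum_mode$relative_height, c(2, 10, 3) / 15)

  single <- list(heights = c(0, 7, 0), offset = 1L)
  one <- relative_heights(detect_candidate_peaks(single), single, "peak_sum")
  expect_equal(one$relative_height, 1)

  pair <- list(heights = c(0, 4, 0, 4, 0), offset = 1L)
  two <- relative_heights(detect_candidate_peaks(pair), pair, "peak_sum")
  expect_equal(two$relative_height, c(0.5, 0.5))

  expect_error(relative_heights(cand, list(heights = c(0, 0), offset = 1L)),
               "no depth", class = "msipeaks_validation_error")
})

test_that("find_peaks composes the pipeline and reports repeat-length positions", {
  one <- find_peaks(hist1(25, 100), hyperparameters())
  expect_equal(one$position, 25L)

  empty <- find_peaks(hist1(integer(0), integer(0)), hyperparameters())
  expect_equal(nrow(empty), 0)

  # planted bimodal with stutter: both modes back, nothing else
  h <- simulate_histogram(
    dplyr::bind_rows(allele_model(18, 400), allele_model(25, 400)),
    seed = 77, marker = "m")
  found <- find_peaks(h, hyperparameters(smoothing = TRUE, r_h = 0.2))
  expect_equal(found$position, c(18L, 25L))

  # raising the threshold past the smaller mode's relative height leaves one
  h2 <- simulate_histogram(
    dplyr::bind_rows(allele_model(25, 800), allele_model(18, 200)),
    seed = 78, marker = "m")
  low <- find_peaks(h2, hyperparameters(r_h = 0.2))
  expect_equal(low$position, c(18L, 25L))
  minor_rh <- low$relative_height[low$position == 18L]
  high <- find_peaks(h2, hyperparameters(r_h = minor_rh + 0.1))
  expect_equal(high$position, 25L)
})

test_that("retained peak count is non-increasing in the threshold", {
  set.seed(505)
  grid <- seq(0.1, 3.0, by = 0.1)
  for (i in 1:100) {
    h <- random_histogram()
    for (sm in c(TRUE, FALSE)) {
      counts <- vapply(grid, function(t) {
        nrow(find_peaks(h, hyperparameters(smoothing = sm, r_h = t)))
      }, numeric(1))
      expect_true(all(diff(counts) <= 0))
    }
  }
})

test_that("peak positions are invariant under uniform scaling of heights", {
  set.seed(606)
  for (i in 1:50) {
    h <- random_histogram()
    for (mode in c("mean_nonzero_bins", "peak_sum")) {
      hp <- hyperparameters(r_h = 0.15, denominator_mode = mode)
      base <- find_peaks(h, hp)
      scaled <- find_peaks(dplyr::mutate(h, count = count * 17L), hp)
      expect_equal(scaled$position, base$position)
      expect_equal(scaled$relative_height, base$relative_height)
    }
  }
})

test_that("smoothing plus the default threshold removes isolated one-read noise", {
  set.seed(707)
  for (i in 1:20) {
    main <- 25L
    # stray positions kept >= 4 apart so each is an isolated spike
    noise_at <- sample(c(10L, 14L, 18L, 32L, 36L, 40L, 44L), 3)
    h <- hist1(c(main - 1L, main, main + 1L, noise_at),
               c(40L, 200L, 40L, 1L, 1L, 1L))
    found <- find_peaks(h, hyperparameters(smoothing = TRUE, r_h = 0.2))
    expect_equal(found$position, main)
    # without smoothing or thresholding, the stray single reads are peaks
    raw <- find_peaks(h, hyperparameters(smoothing = FALSE, r_h = 1e-6))
    expect_true(all(noise_at %in% raw$position))
  }
})
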