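# independent windowed-median oracle with replicate padding
brute_median_filter <- function(x, size = 3L) {
  half <- size %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    win <- x[pmin(pmax(seq(i - half, i + half), 1L), n)]
    median(win)
  }, numeric(1))
}

test_that("median filter removes isolated errors and restores run gaps", {
  expect_equal(median_filter_1d(c(0, 1, 0, 0)), c(0, 0, 0, 0))
  expect_equal(median_filter_1d(c(1, 0, 1, 1)), c(1, 1, 1, 1))
  expect_equal(median_filter_1d(c(0, 1, 1, 0, 0)), c(0, 1, 1, 0, 0))
  expect_identical(median_filter_1d(c(1, 0, 1), size = 1), c(1, 0, 1))
  expect_error(median_filter_1d(c(0, 1), size = 2), "odd")
  expect_error(median_filter_1d(numeric(0)), "empty")
})

test_that("sequences whose runs reach the window size are fixed points", {
  # exhaustively over binary sequences: when every run of 0s and 1s has
  # length >= 3, a size-3 filter leaves the sequence unchanged, so applying
  # it twice equals applying it once
  for (len in 1:10) {
    grid <- as.matrix(expand.grid(rep(list(0:1), len)))
    for (r in seq_len(nrow(grid))) {
      x <- as.numeric(grid[r, ])
      if (any(rle(x)$lengths < 3)) next
      once <- median_filter_1d(x)
      expect_identical(once, x)
      expect_identical(median_filter_1d(once), once)
    }
  }
})

test_that("any-positive after a size-3 filter detects windows with two positives", {
  # the filtered sequence contains a positive exactly when some padded
  # window of three slices holds at least two positives (adjacent pairs,
  # 1-0-1 patterns, and replicate-padded boundary positives)
  for (len in 1:12) {
    grid <- as.matrix(expand.grid(rep(list(0:1), len)))
    for (r in seq_len(nrow(grid))) {
      x <- as.numeric(grid[r, ])
      filtered_pos <- any(median_filter_1d(x) == 1)
      padded <- c(x[1], x, x[len])
      window2 <- any(padded[1:len] + padded[2:(len + 1)] +
                       padded[3:(len + 2)] >= 2)
      expect_identical(filtered_pos, window2)
    }
  }
})

test_that("ASAS labeling follows the two clauses", {
  expect_true(asas_label(c(0, 2, 0)))
  expect_true(asas_label(c(1, 1, 0)))
  expect_false(asas_label(c(1, 0, 1, 0)))
  expect_false(asas_label(c(0, 0, 0)))
  expect_true(asas_label(c(0, 0, 1, 1)))
  expect_false(asas_label(integer(0)))
  expect_error(asas_label(c(-1, 0)), "non-negative")
})

test_that("subject decision rules behave as specified", {
  expect_identical(subject_decision(c(0, 0, 0)), 0L)
  expect_identical(subject_decision(c(0, 1, 1, 1, 0)), 1L)
  expect_identical(subject_decision(c(0, 1, 1, 1, 0), "mean_threshold",
                                    tau = 0.5), 1L)
  filt <- median_filter_1d(c(0, 1, 0, 0, 0))
  expect_identical(subject_decision(filt), 0L)
  expect_error(subject_decision(numeric(0)), "empty")
})

test_that("error-free slice predictions reproduce the ASAS subject labels", {
  co <- generate_cohort(4, 4, phantom_params(), seed = 17)
  for (ex in co$subjects) {
    labels <- vapply(ex$slices, function(s) s$slice_label, integer(1))
    filt <- median_filter_1d(labels)
    expect_identical(subject_decision(filt), ex$subject_label)
  }
})

test_that("prediction sequences group by subject and preserve slice order", {
  sid <- c("b", "b", "a", "a", "a")
  six <- c(1L, 0L, 2L, 0L, 1L)
  sc <- c(0.9, 0.8, 0.1, 0.95, 0.9)
  out <- prediction_sequences(sid, six, sc)
  expect_identical(out$subject_id, c("a", "a", "a", "b", "b"))
  expect_identical(out$slice_index, c(0L, 1L, 2L, 0L, 1L))
  a <- out[out$subject_id == "a", ]
  expect_identical(a$raw, c(1L, 1L, 0L))
  expect_identical(unique(a$subject_diagnosis), 1L)
})
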