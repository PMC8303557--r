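test_that("negative subjects have the configured slice counts and no lesions", {
  p <- phantom_params()
  ex <- generate_subject(p, positive = FALSE, seed = 1)
  n <- length(ex$slices)
  expect_gte(n, 18)
  expect_lte(n, 25)
  expect_equal(ex$subject_label, 0L)
  for (s in ex$slices) {
    expect_equal(s$slice_label, 0L)
    expect_length(s$lesion_masks, 0)
  }
})

test_that("positive subjects satisfy the ASAS rule with consecutive lesioned slices", {
  p <- phantom_params()
  for (seed in c(2, 9, 31)) {
    ex <- generate_subject(p, positive = TRUE, seed = seed)
    n <- length(ex$slices)
    expect_gte(n, 4)
    expect_lte(n, 23)
    expect_equal(ex$subject_label, 1L)
    counts <- vapply(ex$slices, function(s) length(s$lesion_masks), integer(1))
    expect_true(asas_label(counts))
    pos <- counts >= 1
    expect_true(any(pos[-n] & pos[-1]) || max(counts) >= 2)
    for (s in ex$slices)
      expect_identical(s$slice_label, as.integer(length(s$lesion_masks) > 0))
  }
})

test_that("slice annotations are geometrically valid", {
  ex <- generate_subject(phantom_params(), positive = TRUE, seed = 7)
  for (s in ex$slices) {
    d <- dim(s$image)
    for (b in list(s$left_box, s$right_box)) {
      expect_gte(b$r0, 0); expect_gte(b$c0, 0)
      expect_lte(b$r1, d[1]); expect_lte(b$c1, d[2])
      expect_gt(bbox_width(b), 0); expect_gt(bbox_height(b), 0)
    }
    expect_lte(s$left_box$c1, s$right_box$c0)  # non-overlapping
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
  idx <- vapply(ex$slices, function(s) s$slice_index, integer(1))
  expect_identical(idx, seq_along(ex$slices) - 1L)
})

test_that("generation is bit-identical for a fixed seed", {
  p <- phantom_params()
  a <- generate_subject(p, TRUE, seed = 5)
  b <- generate_subject(p, TRUE, seed = 5)
  expect_identical(a, b)
  ca <- generate_cohort(2, 2, p, seed = 8)
  cb <- generate_cohort(2, 2, p, seed = 8)
  expect_identical(ca, cb)
})

test_that("lesion pixels are brighter than bone by at least half the contrast", {
  p <- phantom_params(rician_sigma = 0)  # pre-noise intensities
  ex <- generate_subject(p, TRUE, seed = 3)
  for (s in ex$slices) {
    if (length(s$lesion_masks) == 0) next
    un <- Reduce(`|`, s$lesion_masks)
    bone <- s$image == p$bone_intensity & !un
    expect_gte(mean(s$image[un]) - mean(s$image[bone]), p$lesion_contrast / 2)
  }
})

test_that("lesion centers drift slowly between adjacent slices", {
  ex <- generate_subject(phantom_params(), TRUE, seed = 13)
  centroid <- function(m) {
    w <- which(m, arr.ind = TRUE)
    colMeans(w)
  }
  prev <- NULL
  for (s in ex$slices) {
    if (length(s$lesion_masks) == 0) { prev <- NULL; next }
    cur <- centroid(s$lesion_masks[[1]])
    if (!is.null(prev))
      expect_lte(sqrt(sum((cur - prev)^2)), 4)
    prev <- cur
  }
})

test_that("cohort composition and manifest bookkeeping are exact", {
  co <- generate_cohort(2, 2, phantom_params(), seed = 4)
  expect_length(co$subjects, 4)
  labs <- vapply(co$subjects, function(e) e$subject_label, integer(1))
  expect_equal(sum(labs == 1), 2)
  expect_equal(sum(labs == 0), 2)
  n_slices <- vapply(co$subjects, function(e) length(e$slices), integer(1))
  expect_equal(nrow(co$manifest), sum(n_slices))
  one <- generate_cohort(0, 1, phantom_params(), seed = 2)
  expect_length(one$subjects, 1)
  expect_true(all(one$manifest$slice_label == 0))
})

test_that("manifest round-trips through CSV exactly", {
  co <- generate_cohort(1, 1, phantom_params(), seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(co$manifest, path)
  back <- read_manifest(path)
  expect_identical(back, co$manifest)
})

test_that("a written cohort reads back with identical annotations", {
  co <- generate_cohort(1, 1, phantom_params(), seed = 9)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(back$manifest, manifest)
  orig <- co$subjects[[which(vapply(co$subjects, function(e) e$subject_id,
                                    character(1)) == back$subjects[[1]]$subject_id)]]
  s0 <- back$subjects[[1]]$slices[[1]]
  o0 <- orig$slices[[1]]
  expect_identical(s0$left_box, o0$left_box)
  expect_identical(s0$slice_label, o0$slice_label)
  # 8-bit quantization at PNG export
  expect_lt(max(abs(s0$image - o0$image)), 1 / 255)
  expect_length(s0$lesion_masks, length(o0$lesion_masks))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(image_size = c(32, 32)), "64x64")
  expect_error(phantom_params(lesion_contrast = 0), "contrast")
  expect_error(phantom_params(n_slices_range_pos = c(5, 3)), "range")
})
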