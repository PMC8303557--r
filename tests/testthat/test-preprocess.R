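test_that("ROI boxes follow the medial-shift construction", {
  rb <- compute_roi_boxes(bbox(20, 80, 10, 50), bbox(20, 80, 60, 100),
                          shift_fraction = 0.8)
  # left box cols [10,50): width 40, center 30 -> ROI cols [30, 62)
  expect_identical(rb$left_roi$c0, 30L)
  expect_identical(rb$left_roi$c1, 62L)
  expect_identical(rb$left_roi$r0, 20L)
  expect_identical(rb$left_roi$r1, 80L)
  # right box [60,100): mirror-consistent center 79 -> ROI cols (47, 79]
  expect_identical(rb$right_roi$c0, 48L)
  expect_identical(rb$right_roi$c1, 80L)
})

test_that("degenerate ROI requests are rejected", {
  expect_error(compute_roi_boxes(bbox(0, 10, 5, 5), bbox(0, 10, 20, 30)),
               "degenerate")
  expect_error(compute_roi_boxes(bbox(0, 10, 0, 10), bbox(0, 10, 20, 30),
                                 shift_fraction = 0), "zero width")
  expect_error(compute_roi_boxes(bbox(0, 10, 0, 25), bbox(0, 10, 20, 30)),
               "left")
})

test_that("symmetric iliac boxes give mirror-image ROIs", {
  W <- 100L
  left <- bbox(10, 60, 10, 40)
  right <- bbox(10, 60, W - 40, W - 10)
  rb <- compute_roi_boxes(left, right)
  # reflect the left ROI about the midline: col c -> W - c (half-open flips)
  expect_identical(rb$right_roi$c0, W - rb$left_roi$c1)
  expect_identical(rb$right_roi$c1, W - rb$left_roi$c0)
  # and the extracted patches mirror each other on a symmetric image
  img <- matrix(runif(80 * W), 80, W)
  img_sym <- (img + img[, W:1]) / 2
  patch <- extract_roi_patch(img_sym, rb)
  lcrop <- img_sym[(rb$left_roi$r0 + 1):rb$left_roi$r1,
                   (rb$left_roi$c0 + 1):rb$left_roi$c1]
  rcrop <- img_sym[(rb$right_roi$r0 + 1):rb$right_roi$r1,
                   (rb$right_roi$c0 + 1):rb$right_roi$c1]
  expect_equal(lcrop, rcrop[, rev(seq_len(ncol(rcrop)))])
  expect_identical(patch$image, cbind(lcrop, rcrop))
})

test_that("patch combination copies source pixels and height-matches crops", {
  img <- matrix(seq_len(100 * 120) / (100 * 120), 100, 120)
  rb <- compute_roi_boxes(bbox(20, 80, 10, 40), bbox(30, 80, 70, 100),
                          shift_fraction = 0.8, image_size = dim(img))
  patch <- extract_roi_patch(img, rb)
  # heights differ (60 vs 50): the shorter side is extended to 60 rows
  expect_identical(bbox_height(patch$left_roi), bbox_height(patch$right_roi))
  expect_identical(nrow(patch$image), 60L)
  expect_identical(ncol(patch$image),
                   bbox_width(rb$left_roi) + bbox_width(rb$right_roi))
  # symmetric extension: rows [25, 85) around the original [30, 80)
  expect_identical(patch$right_roi$r0, 25L)
  expect_identical(patch$right_roi$r1, 85L)
  # no interpolation: every patch pixel equals its source pixel
  wl <- bbox_width(patch$left_roi)
  expect_identical(patch$image[, seq_len(wl)],
                   img[(patch$left_roi$r0 + 1):patch$left_roi$r1,
                       (patch$left_roi$c0 + 1):patch$left_roi$c1])
  expect_identical(patch$image[, wl + seq_len(bbox_width(patch$right_roi))],
                   img[(patch$right_roi$r0 + 1):patch$right_roi$r1,
                       (patch$right_roi$c0 + 1):patch$right_roi$c1])
})

test_that("ROI geometry is translation-equivariant", {
  img <- matrix(runif(96 * 96), 96, 96)
  l <- bbox(20, 70, 10, 36); r <- bbox(20, 70, 60, 86)
  p0 <- extract_roi_patch(img, compute_roi_boxes(l, r))$image
  dr <- 4L; dc <- 6L
  big <- matrix(0, 120, 120)
  big[(1:96) + dr, (1:96) + dc] <- img
  l2 <- bbox(l$r0 + dr, l$r1 + dr, l$c0 + dc, l$c1 + dc)
  r2 <- bbox(r$r0 + dr, r$r1 + dr, r$c0 + dc, r$c1 + dc)
  p1 <- extract_roi_patch(big, compute_roi_boxes(l2, r2))$image
  expect_identical(p0, p1)
})

test_that("scanner noise with all components disabled is the identity", {
  img <- matrix(runif(50 * 50), 50, 50)
  out <- add_scanner_noise(img, noise_params(gaussian_variance = 0,
                                             poisson_rule = "none"))
  expect_identical(out, img)
})

test_that("scanner noise is deterministic for a fixed seed", {
  img <- matrix(runif(40 * 40), 40, 40)
  np <- noise_params(gaussian_variance = 0.01, seed = 123)
  expect_identical(add_scanner_noise(img, np), add_scanner_noise(img, np))
})

test_that("the Gaussian component has the configured variance", {
  img <- matrix(0.5, 1000, 1000)
  np <- noise_params(gaussian_variance = 0.01, poisson_rule = "none",
                     clip = FALSE, seed = 42)
  d <- add_scanner_noise(img, np) - img
  expect_lt(abs(var(as.vector(d)) - 0.01), 0.001)
  expect_lt(abs(mean(d)), 3 * 0.1 / 1000)  # zero mean within 3 SE
})

test_that("the Poisson component matches its single-pixel lambda rule", {
  img <- matrix(0.5, 1000, 1000)
  np <- noise_params(gaussian_variance = 0, poisson_rule = "single_pixel",
                     clip = FALSE, seed = 7)
  d <- add_scanner_noise(img, np) - img
  # constant image: the sampled pixel is 0.5, lambda = log(255*0.5 + 1)^4
  lambda <- log(255 * 0.5 + 1)^4
  se <- sqrt(lambda) / 255 / 1000
  expect_lt(abs(mean(d) - lambda / 255), 3 * se)
})

test_that("bilinear resize preserves structure", {
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(resize_patch(img, c(64, 64)), img, tolerance = 1e-12)
  const <- matrix(0.3, 50, 40)
  out <- resize_patch(const, c(224, 224))
  expect_identical(dim(out), c(224L, 224L))
  expect_equal(range(out), c(0.3, 0.3))
  checker <- outer(1:64, 1:64, function(i, j) (i + j) %% 2)
  down <- resize_patch(checker, c(32, 32))
  expect_lt(abs(mean(down) - mean(checker)) / mean(checker), 0.01)
})

test_that("augmentation flips are involutions and rotations preserve shape", {
  img <- matrix(runif(60 * 48), 60, 48)
  flipped <- augment(img, flip = TRUE, angle = 0)
  expect_identical(augment(flipped, flip = TRUE, angle = 0), img)
  expect_identical(augment(img, flip = FALSE, angle = 0), img)
  set.seed(99)
  for (a in runif(5, -15, 15)) {
    out <- augment(img, flip = FALSE, angle = a)
    expect_identical(dim(out), dim(img))
    expect_true(all(out >= min(img) - 1e-12 & out <= max(img) + 1e-12))
  }
})
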