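test_that("focal loss evaluates its closed form", {
  expect_equal(focal_loss(0.5, alpha = 1, gamma = 0), log(2), tolerance = 1e-9)
  expect_equal(focal_loss(0.9, alpha = 0.25, gamma = 2),
               0.25 * 0.1^2 * -log(0.9), tolerance = 1e-12)
  expect_equal(focal_loss(0.9, alpha = 0.25, gamma = 2), 2.634e-4,
               tolerance = 1e-3)
  # monotone decreasing in p, non-negative, and -> 0 as p -> 1
  p <- seq(0.05, 0.999, length.out = 200)
  l <- focal_loss(p)
  expect_true(all(diff(l) < 0))
  expect_true(all(l >= 0))
  expect_lt(focal_loss(1 - 1e-9), 1e-8)
  expect_error(focal_loss(0.5, alpha = 0), "alpha")
  expect_error(focal_loss(0.5, gamma = -1), "gamma")
})

test_that("cosine schedule starts at lr0, halves at midpoint, ends at lr_min", {
  expect_equal(cosine_lr(0, 50), 0.03)
  expect_equal(cosine_lr(50, 50), 0)
  expect_equal(cosine_lr(25, 50), 0.015)
  expect_equal(cosine_lr(10, 20, lr0 = 0.2, lr_min = 0.02), 0.11)
  expect_error(cosine_lr(51, 50), "t must")
  expect_error(cosine_lr(0, 0), "total")
})

test_that("classifier construction is deterministic and counts its depth", {
  cfg <- classifier_config("tiny", seed = 11)
  a <- build_classifier(cfg)
  b <- build_classifier(cfg)
  expect_identical(a$layers, b$layers)
  r18 <- build_classifier(classifier_config("resnet18"))
  expect_identical(r18$n_weighted, 18L)
  expect_error(build_classifier(classifier_config("tiny", pretrained = TRUE)),
               "weights_file")
})

test_that("an untrained net with a zeroed output layer scores 0.5", {
  clf <- build_classifier(classifier_config("tiny", seed = 1))
  last <- length(clf$layers)
  clf$layers[[last]]$w[] <- 0
  clf$layers[[last]]$b[] <- 0
  expect_equal(predict_slice(clf, matrix(0, 64, 64)), 0.5)
  s <- predict_slice(clf, matrix(runif(64 * 64), 64, 64))
  expect_equal(s, 0.5)
})

test_that("prediction scores stay in [0,1] and enforce the input size", {
  clf <- build_classifier(classifier_config("tiny", seed = 2))
  s <- predict_slices(clf, lapply(1:3, function(i) matrix(runif(64^2), 64, 64)))
  expect_true(all(s >= 0 & s <= 1))
  expect_error(predict_slice(clf, matrix(0, 32, 32)), "expects")
})

test_that("training history records the cosine schedule and epoch count", {
  toy <- toy_patch_set(4)
  cfg <- classifier_config("tiny", epochs = 3, seed = 4)
  clf <- train_classifier(build_classifier(cfg), toy$x, toy$y)
  expect_identical(nrow(clf$history), 3L)
  expect_equal(clf$history$lr, cosine_lr(0:2, 3, cfg$initial_lr))
  one <- train_classifier(build_classifier(cfg), toy$x, toy$y, epochs = 1)
  expect_identical(nrow(one$history), 1L)
})

test_that("a single-class training set warns but proceeds", {
  toy <- toy_patch_set(3)
  keep <- toy$y == 0
  cfg <- classifier_config("tiny", epochs = 1, seed = 4)
  expect_warning(train_classifier(build_classifier(cfg), toy$x[keep],
                                  toy$y[keep]),
                 "single class")
})

test_that("the tiny backbone separates high-contrast toy patches", {
  toy <- toy_patch_set(20)
  cfg <- classifier_config("tiny", epochs = 10, initial_lr = 0.15, seed = 6)
  clf <- train_classifier(build_classifier(cfg), toy$x, toy$y)
  expect_gte(tail(clf$history$train_acc, 1), 0.9)
})

test_that("checkpoints round-trip the trained classifier", {
  toy <- toy_patch_set(3)
  cfg <- classifier_config("tiny", epochs = 1, seed = 4)
  clf <- train_classifier(build_classifier(cfg), toy$x, toy$y)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(clf, path)
  back <- load_checkpoint(path)
  expect_identical(back$layers, clf$layers)
  expect_identical(predict_slices(back, toy$x[1:4]),
                   predict_slices(clf, toy$x[1:4]))
})

test_that("flip augmentation yields flip-consistent decisions", {
  fx <- trained_pipeline_fixture()
  te <- fx$dataset$subject_id %in% fx$fold$test_subjects
  xs <- fx$dataset$x[te]
  sc <- predict_slices(fx$classifier, xs)
  flipped <- lapply(xs, function(m) m[, rev(seq_len(ncol(m)))])
  scf <- predict_slices(fx$classifier, flipped)
  agree <- mean((sc > 0.5) == (scf > 0.5))
  expect_gte(agree, 0.9)
})
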