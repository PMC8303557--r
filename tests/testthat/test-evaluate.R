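test_that("confusion counts follow the 2x2 table", {
  c1 <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_identical(unlist(c1[c("tp", "tn", "fp", "fn")]),
                   c(tp = 2L, tn = 2L, fp = 0L, fn = 0L))
  c2 <- confusion(c(1, 1, 1, 1), c(1, 0, 1, 0))
  expect_identical(unlist(c2[c("tp", "tn", "fp", "fn")]),
                   c(tp = 2L, tn = 0L, fp = 2L, fn = 0L))
  expect_error(confusion(integer(0), integer(0)), "empty")
  expect_error(confusion(c(1, 0), c(1)), "lengths")
  expect_error(confusion(c(2, 0), c(1, 0)), "binary")
})

test_that("metrics match hand arithmetic and handle undefined ratios", {
  m <- metrics_from_confusion(list(tp = 19, fn = 0, tn = 5, fp = 1))
  expect_equal(m$recall, 100)
  expect_equal(m$npv, 100)
  m2 <- metrics_from_confusion(list(tp = 9, fn = 1, tn = 8, fp = 2))
  expect_equal(m2$accuracy, 85)
  expect_equal(m2$precision, 81.82, tolerance = 1e-4)
  expect_equal(m2$specificity, 80)
  expect_equal(m2$f1, 85.71, tolerance = 1e-4)
  m3 <- metrics_from_confusion(list(tp = 0, fn = 0, tn = 5, fp = 2))
  expect_true(is.na(m3$recall))
  expect_error(metrics_from_confusion(list(tp = 0, fn = 0, tn = 0, fp = 0)),
               "all-zero")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(5)
  for (i in 1:50) {
    counts <- list(tp = rpois(1, 10) + 1, tn = rpois(1, 10) + 1,
                   fp = rpois(1, 5), fn = rpois(1, 5))
    m <- metrics_from_confusion(counts)
    n <- counts$tp + counts$tn + counts$fp + counts$fn
    expect_equal(m$accuracy * n / 100, counts$tp + counts$tn, tolerance = 1e-9)
    expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                 tolerance = 1e-9)
  }
})

test_that("rank-statistic AUC matches known values and pROC", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
  skip_if_not_installed("pROC")
  set.seed(9)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- round(runif(n), 2)  # ties likely
    ref <- as.numeric(pROC::auc(pROC::roc(truth, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(sc, truth), ref, tolerance = 1e-12)
  }
})

test_that("subject-wise folds are stratified, disjoint and exhaustive", {
  ids <- sprintf("S%02d", 1:79)
  labs <- rep(c(1L, 0L), c(60, 19))
  folds <- make_folds(ids, labs, 0.7, 5, seed = 3)
  expect_length(folds, 5)
  for (f in folds) {
    expect_length(intersect(f$train_subjects, f$test_subjects), 0)
    expect_setequal(c(f$train_subjects, f$test_subjects), ids)
    tr_lab <- labs[match(f$train_subjects, ids)]
    expect_equal(sum(tr_lab == 1), 42)  # round(0.7 * 60)
    expect_equal(sum(tr_lab == 0), 13)  # round(0.7 * 19)
  }
  expect_length(make_folds(ids, labs, n_repeats = 1, seed = 1), 1)
  expect_error(make_folds(c("a", "b", "c"), c(1, 1, 0)), "2 subjects")
})

test_that("fold summaries report mean and sample standard deviation", {
  reps <- data.frame(accuracy = c(90, 92, 94), recall = c(100, 100, 100))
  s <- summarize_folds(reps)
  expect_equal(s$mean[s$metric == "accuracy"], 92)
  expect_equal(s$sd[s$metric == "accuracy"], 2)
  expect_equal(s$sd[s$metric == "recall"], 0)
  one <- summarize_folds(data.frame(accuracy = 88))
  expect_equal(one$mean, 88)
  expect_equal(one$sd, 0)
  expect_equal(one$n, 1L)
  ident <- summarize_folds(data.frame(accuracy = rep(91.5, 4)))
  expect_equal(ident$sd, 0)
})
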