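# Shared fixtures. The trained-pipeline fixture is expensive (one classifier
# trained on a 20-subject phantom cohort), so it is built lazily and cached
# for the whole test run.

tiny_train_config <- function(epochs = 15L, seed = 5L) {
  classifier_config("tiny", epochs = epochs, initial_lr = 0.15, seed = seed)
}

trained_pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cohort <- generate_cohort(10, 10, phantom_params(), seed = 20)
    dataset <- build_patch_dataset(cohort$subjects, keep_masks = TRUE)
    ids <- vapply(cohort$subjects, function(e) e$subject_id, character(1))
    labs <- vapply(cohort$subjects, function(e) e$subject_label, integer(1))
    fold <- make_folds(ids, labs, 0.7, 1, seed = 11)[[1]]
    rf <- run_fold(dataset, fold, tiny_train_config())
    cache <<- list(cohort = cohort, dataset = dataset, fold = fold,
                   classifier = rf$classifier, sequences = rf$sequences,
                   report = rf$report)
    cache
  }
})

# A quickly separable toy patch set: bright disk on bone-like background
# versus background only.
toy_patch_set <- function(n_per_class = 20, size = 64, seed = 3) {
  set.seed(seed)
  make <- function(lesion) {
    img <- matrix(0.4 + rnorm(size * size, 0, 0.02), size, size)
    if (lesion) {
      r0 <- sample(20:44, 1); c0 <- sample(20:44, 1)
      rr <- matrix(seq_len(size), size, size)
      cc <- t(rr)
      img[(rr - r0)^2 + (cc - c0)^2 <= 16] <- 0.95
    }
    pmin(pmax(img, 0), 1)
  }
  x <- c(lapply(seq_len(n_per_class), function(i) make(TRUE)),
         lapply(seq_len(n_per_class), function(i) make(FALSE)))
  list(x = x, y = rep(c(1L, 0L), each = n_per_class))
}
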