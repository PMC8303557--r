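#' Build the classifier dataset from a cohort
#'
#' Applies the pipeline preprocessing to every slice of every subject:
#' scanner-noise injection (identical procedure for all images regardless of
#' later train/test membership), ROI patch construction from the iliac
#' bounding boxes, and bilinear resizing to the classifier input size. In
#' `"ori"` mode the whole slice is resized instead of the ROI patch, which
#' reproduces the original-image baseline.
#'
#' @param subjects list of `subject_exam` objects.
#' @param mode `"roi"` (default) or `"ori"`.
#' @param target_size classifier input size (default 64x64, matching the
#'   `"tiny"` backbone).
#' @param noise a [noise_params()] object. The default used here for phantom
#'   experiments is mild Gaussian noise (variance 0.01, no Poisson
#'   component); see the methods vignette for why the published variance of
#'   0.3 is kept only as the [noise_params()] default.
#' @param shift_fraction ROI shift fraction (see [compute_roi_boxes()]).
#' @param noise_seed base seed for the per-slice noise streams.
#' @param keep_masks also carry each slice's lesion-mask union through the
#'   same geometry (crop + resize), for saliency validation.
#' @return List with parallel per-slice vectors/lists: `x` (patch matrices),
#'   `y` (slice labels), `subject_id`, `slice_index`, `subject_label`, and
#'   optionally `mask`.
#' @export
build_patch_dataset <- function(subjects, mode = c("roi", "ori"),
                                target_size = c(64L, 64L),
                                noise = noise_params(gaussian_variance = 0.01,
                                                     poisson_rule = "none"),
                                shift_fraction = 0.8, noise_seed = 1L,
                                keep_masks = FALSE) {
  mode <- match.arg(mode)
  x <- list(); y <- integer(0); sid <- character(0); six <- integer(0)
  slab <- integer(0); msk <- list()
  counter <- 0L
  for (ex in subjects) {
    for (s in ex$slices) {
      counter <- counter + 1L
      np <- noise
      np$seed <- noise_seed + counter
      img <- add_scanner_noise(s$image, np)
      lesion_union <- NULL
      if (keep_masks) {
        lesion_union <- matrix(0, nrow(img), ncol(img))
        for (m in s$lesion_masks) lesion_union <- pmax(lesion_union, m * 1)
      }
      if (mode == "roi") {
        rois <- compute_roi_boxes(s$left_box, s$right_box, shift_fraction,
                                  image_size = dim(img))
        patch <- resize_patch(extract_roi_patch(img, rois), target_size)$image
        if (keep_masks) {
          mp <- extract_roi_patch(lesion_union, rois)$image
          lesion_union <- resize_patch(mp, target_size) > 0.2
        }
      } else {
        patch <- resize_patch(img, target_size)
        if (keep_masks)
          lesion_union <- resize_patch(lesion_union, target_size) > 0.2
      }
      x[[counter]] <- patch
      y[counter] <- s$slice_label
      sid[counter] <- s$subject_id
      six[counter] <- s$slice_index
      slab[counter] <- ex$subject_label
      if (keep_masks) msk[[counter]] <- lesion_union
    }
  }
  out <- list(x = x, y = y, subject_id = sid, slice_index = six,
              subject_label = slab)
  if (keep_masks) out$mask <- msk
  out
}

#' Train and evaluate one fold
#'
#' Trains a fresh classifier on the fold's training subjects and evaluates on
#' its test subjects: slice metrics before and after the median filter,
#' subject-level metrics under the configured decision rule, and the slice
#' ROC AUC.
#'
#' @param dataset output of [build_patch_dataset()].
#' @param fold a `fold_split` from [make_folds()].
#' @param config a [classifier_config()]; the classifier seed is offset by
#'   the repeat index so folds differ.
#' @param filter_size median-filter window (default 3).
#' @param rule,tau subject decision rule (see [subject_decision()]).
#' @param epochs optional override of `config$epochs`.
#' @return List with `report` (one-row data.frame of fold metrics),
#'   `sequences` (per-slice prediction data.frame), `classifier`.
#' @export
run_fold <- function(dataset, fold, config, filter_size = 3L,
                     rule = "any_positive", tau = 0, epochs = NULL) {
  tr <- dataset$subject_id %in% fold$train_subjects
  te <- dataset$subject_id %in% fold$test_subjects
  if (!any(tr) || !any(te)) stop("fold has empty train or test partition")
  cfg <- config
  cfg$seed <- config$seed + fold$repeat_index
  clf <- build_classifier(cfg)
  clf <- train_classifier(clf, dataset$x[tr], dataset$y[tr], epochs = epochs)
  scores <- predict_slices(clf, dataset$x[te])
  truth <- dataset$y[te]
  seqs <- prediction_sequences(dataset$subject_id[te], dataset$slice_index[te],
                               scores, threshold = cfg$threshold,
                               filter_size = filter_size, rule = rule,
                               tau = tau)
  # align sequences back to slice truth
  key <- paste(dataset$subject_id[te], dataset$slice_index[te])
  ord <- match(paste(seqs$subject_id, seqs$slice_index), key)
  truth_seq <- truth[ord]
  slice_raw <- metrics_from_confusion(confusion(seqs$raw, truth_seq))
  slice_filt <- metrics_from_confusion(confusion(seqs$filtered, truth_seq))
  sub_pred <- vapply(split(seqs$subject_diagnosis, seqs$subject_id),
                     function(v) v[1], numeric(1))
  sub_truth <- vapply(split(dataset$subject_label[te][ord],
                            seqs$subject_id),
                      function(v) v[1], numeric(1))
  sub_metrics <- metrics_from_confusion(confusion(sub_pred, sub_truth))
  auc <- if (length(unique(truth_seq)) == 2L) roc_auc(seqs$score, truth_seq)
         else NA_real_
  report <- data.frame(fold = fold$repeat_index, auc = auc)
  for (nm in names(slice_raw)) report[[paste0("slice_", nm)]] <- slice_raw[[nm]]
  for (nm in names(slice_filt))
    report[[paste0("slice_filtered_", nm)]] <- slice_filt[[nm]]
  for (nm in names(sub_metrics))
    report[[paste0("subject_", nm)]] <- sub_metrics[[nm]]
  list(report = report, sequences = seqs, classifier = clf)
}

#' Run the repeated hold-out experiment on a cohort
#'
#' The full pipeline: preprocess all slices once, draw `n_repeats`
#' subject-wise stratified 70/30 splits, train and evaluate a classifier per
#' fold, and aggregate the fold metrics as mean +/- standard deviation.
#'
#' @param cohort list with `subjects` (and `manifest`), e.g. from
#'   [generate_cohort()].
#' @param config a [classifier_config()].
#' @param n_repeats number of splits (default 5).
#' @param train_fraction per-class training fraction (default 0.7).
#' @param seed seed for the splits.
#' @param mode,target_size,noise,shift_fraction,noise_seed passed to
#'   [build_patch_dataset()].
#' @param filter_size,rule,tau passed to [run_fold()].
#' @param epochs optional override of `config$epochs`.
#' @param keep_classifiers retain the per-fold classifiers in the result.
#' @return List with `per_fold` (data.frame, one row per fold), `summary`
#'   (from [summarize_folds()]), `sequences` (per-fold prediction
#'   data.frames) and optionally `classifiers`.
#' @export
run_experiment <- function(cohort, config, n_repeats = 5L,
                           train_fraction = 0.7, seed = 1L,
                           mode = "roi", target_size = c(64L, 64L),
                           noise = noise_params(gaussian_variance = 0.01,
                                                poisson_rule = "none"),
                           shift_fraction = 0.8, noise_seed = 1L,
                           filter_size = 3L, rule = "any_positive", tau = 0,
                           epochs = NULL, keep_classifiers = FALSE) {
  dataset <- build_patch_dataset(cohort$subjects, mode = mode,
                                 target_size = target_size, noise = noise,
                                 shift_fraction = shift_fraction,
                                 noise_seed = noise_seed)
  sub_ids <- vapply(cohort$subjects, function(e) e$subject_id, character(1))
  sub_lab <- vapply(cohort$subjects, function(e) e$subject_label, integer(1))
  folds <- make_folds(sub_ids, sub_lab, train_fraction, n_repeats, seed)
  results <- lapply(folds, function(f)
    run_fold(dataset, f, config, filter_size, rule, tau, epochs))
  per_fold <- do.call(rbind, lapply(results, function(r) r$report))
  out <- list(per_fold = per_fold,
              summary = summarize_folds(per_fold[, -1, drop = FALSE]),
              sequences = lapply(results, function(r) r$sequences),
              folds = folds)
  if (keep_classifiers)
    out$classifiers <- lapply(results, function(r) r$classifier)
  out
}
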