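#' Confusion counts
#'
#' @param pred,truth binary vectors (0/1) of equal, non-zero length.
#' @return Object of class `confusion_counts` with fields `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (length(pred) == 0L) stop("empty vectors")
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (!all(pred %in% 0:1) || !all(truth %in% 0:1))
    stop("pred and truth must be binary (0/1)")
  structure(list(tp = sum(pred == 1L & truth == 1L),
                 tn = sum(pred == 0L & truth == 0L),
                 fp = sum(pred == 1L & truth == 0L),
                 fn = sum(pred == 0L & truth == 1L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion TP=%d TN=%d FP=%d FN=%d>\n", x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic metrics from a confusion table
#'
#' Computes accuracy, recall (sensitivity), precision, specificity, negative
#' predictive value (`TN / (TN + FN)`) and F1 score, all as percentages.
#' A metric whose denominator is zero is reported as `NA` (undefined) rather
#' than 0, so fold averages are not silently deflated.
#'
#' @param counts a [confusion()] object (or list with tp/tn/fp/fn).
#' @return Named list of percentages: `accuracy`, `recall`, `precision`,
#'   `specificity`, `npv`, `f1`.
#' @export
metrics_from_confusion <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("all-zero confusion table")
  recall <- safe_ratio(tp, tp + fn)
  precision <- safe_ratio(tp, tp + fp)
  f1 <- if (is.na(recall) || is.na(precision) || (precision + recall) == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(accuracy = 100 * (tp + tn) / total,
       recall = 100 * recall,
       precision = 100 * precision,
       specificity = 100 * safe_ratio(tn, tn + fp),
       npv = 100 * safe_ratio(tn, tn + fn),
       f1 = 100 * f1)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney rank statistic with ties counted
#' one half, which equals the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric prediction scores.
#' @param truth binary labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth)) stop("scores and truth lengths differ")
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated subject-wise stratified hold-out splits
#'
#' Each repeat draws a fresh random split at the subject level (slices never
#' cross the train/test boundary), stratified by class: `train_fraction` of
#' the positive subjects and of the negative subjects go to training, the
#' rest to test.
#'
#' @param subject_id character vector of subject ids (one entry per subject).
#' @param subject_label binary subject labels (1 = active sacroiliitis).
#' @param train_fraction fraction of each class used for training
#'   (default 0.7).
#' @param n_repeats number of independent splits (default 5).
#' @param seed integer seed.
#' @return List of `fold_split` objects: `repeat_index`, `train_subjects`,
#'   `test_subjects`.
#' @export
make_folds <- function(subject_id, subject_label, train_fraction = 0.7,
                       n_repeats = 5L, seed = 1L) {
  stopifnot(length(subject_id) == length(subject_label))
  if (anyDuplicated(subject_id)) stop("duplicate subject ids")
  subject_label <- as.integer(subject_label)
  pos <- subject_id[subject_label == 1L]
  neg <- subject_id[subject_label == 0L]
  if (length(pos) < 2L || length(neg) < 2L)
    stop("need at least 2 subjects per class")
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(k) {
      take <- function(ids) {
        ntr <- round(train_fraction * length(ids))
        ntr <- max(1L, min(length(ids) - 1L, ntr))
        sample(ids, ntr)
      }
      tr <- c(take(pos), take(neg))
      structure(list(repeat_index = k, train_subjects = sort(tr),
                     test_subjects = sort(setdiff(subject_id, tr))),
                class = "fold_split")
    })
  })
}

#' Aggregate per-fold metric reports
#'
#' @param reports data.frame with one row per fold and one numeric column per
#'   metric (or a list of named metric lists).
#' @return data.frame with columns `metric`, `mean`, `sd` (sample standard
#'   deviation; 0 with `n = 1`) and `n` (number of non-missing folds).
#' @export
summarize_folds <- function(reports) {
  if (!is.data.frame(reports))
    reports <- do.call(rbind, lapply(reports, function(r) as.data.frame(r)))
  if (nrow(reports) == 0L) stop("no fold reports")
  num <- vapply(reports, is.numeric, logical(1))
  out <- do.call(rbind, lapply(names(reports)[num], function(nm) {
    v <- reports[[nm]]
    v <- v[!is.na(v)]
    data.frame(metric = nm, mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else 0,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-fold composition of the reference clinical dataset
#'
#' The published study reports, for each of its five subject-wise 70/30
#' splits, the number of positive/negative slices (and subjects) in the
#' train and test partitions. These printed counts ship with the package as
#' a plain-text table and serve as the reference input for fold bookkeeping
#' checks: within every fold, train + test slices per class must reproduce
#' the cohort totals (422 positive, 393 negative).
#'
#' @return data.frame with columns `fold`, `train_pos`, `train_pos_subjects`,
#'   `train_neg`, `train_neg_subjects`, `test_pos`, `test_pos_subjects`,
#'   `test_neg`, `test_neg_subjects`.
#' @export
fold_composition <- function() {
  path <- system.file("extdata", "fold_composition.csv", package = "sijbme")
  read.csv(path, stringsAsFactors = FALSE)
}
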