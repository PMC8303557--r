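#' 1-D median filter with replicate padding
#'
#' Sliding-window median over a per-subject slice decision sequence, used to
#' enforce the spatial continuity of adjacent MR slices: isolated positives
#' are removed and single missed slices inside a positive run are restored.
#' Both ends are padded by replicating the terminal value, so the output has
#' the input length. Replicate padding (rather than zero padding) never
#' converts a genuine boundary run of two positives into zeros.
#'
#' @param seq numeric/integer vector (binary 0/1 for slice decisions, but any
#'   numeric works).
#' @param size odd window size `>= 1` (default 3).
#' @return Filtered vector of the same length.
#' @examples
#' median_filter_1d(c(0, 1, 0, 0))  # isolated positive removed
#' median_filter_1d(c(1, 0, 1, 1))  # missed slice inside a run restored
#' @export
median_filter_1d <- function(seq, size = 3L) {
  if (length(seq) == 0L) stop("empty sequence")
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("size must be an odd integer >= 1")
  if (size == 1L) return(seq)
  half <- size %/% 2L
  padded <- c(rep(seq[1], half), seq, rep(seq[length(seq)], half))
  vapply(seq_along(seq),
         function(i) median(padded[i:(i + size - 1L)]),
         numeric(1))
}

#' Subject-level ground-truth label under the ASAS rule
#'
#' A subject is positive for active sacroiliitis if there are at least two
#' bone marrow edema lesions on a single slice, or lesions on at least two
#' consecutive slices.
#'
#' @param lesion_counts non-negative integer vector of per-slice lesion
#'   counts, in anatomical slice order.
#' @return `TRUE` (active sacroiliitis) or `FALSE` (normal).
#' @examples
#' asas_label(c(0, 2, 0))     # TRUE: two lesions on one slice
#' asas_label(c(1, 1, 0))     # TRUE: two consecutive slices
#' asas_label(c(1, 0, 1, 0))  # FALSE
#' @export
asas_label <- function(lesion_counts) {
  if (any(lesion_counts < 0)) stop("lesion counts must be non-negative")
  n <- length(lesion_counts)
  if (n == 0L) return(FALSE)
  if (max(lesion_counts) >= 2) return(TRUE)
  if (n >= 2L) {
    pos <- lesion_counts >= 1
    if (any(pos[-n] & pos[-1])) return(TRUE)
  }
  FALSE
}

#' Subject-level diagnosis from the filtered slice sequence
#'
#' The per-subject decision is made on the median-filtered slice decision
#' vector. Under `"any_positive"` (the default) the subject is diagnosed
#' positive if any filtered entry is positive; combined with a size-3 median
#' filter this requires at least two consecutive raw positive slices, which
#' mirrors the ASAS consecutive-slice clause and is maximally sensitive.
#' Under `"mean_threshold"` the subject is positive if the mean of the
#' filtered decisions exceeds `tau`.
#'
#' @param filtered_seq binary vector after [median_filter_1d()].
#' @param rule `"any_positive"` or `"mean_threshold"`.
#' @param tau threshold for the mean rule (default 0, i.e. any positive mass).
#' @return `1L` (active sacroiliitis) or `0L` (normal).
#' @export
subject_decision <- function(filtered_seq,
                             rule = c("any_positive", "mean_threshold"),
                             tau = 0) {
  if (length(filtered_seq) == 0L) stop("empty sequence")
  rule <- match.arg(rule)
  pos <- switch(rule,
                any_positive = any(filtered_seq == 1),
                mean_threshold = mean(filtered_seq) > tau)
  as.integer(pos)
}

#' Per-subject prediction sequences from slice predictions
#'
#' Groups slice-level scores by subject (in slice order), thresholds them,
#' applies the median filter, and takes the subject decision.
#'
#' @param subject_id character vector, one entry per slice.
#' @param slice_index integer slice order within each subject.
#' @param score numeric slice scores.
#' @param threshold decision threshold on the score (default 0.5).
#' @param filter_size median-filter window (default 3).
#' @param rule,tau see [subject_decision()].
#' @return data.frame with one row per slice (`subject_id`, `slice_index`,
#'   `score`, `raw`, `filtered`, `subject_diagnosis`).
#' @export
prediction_sequences <- function(subject_id, slice_index, score,
                                 threshold = 0.5, filter_size = 3L,
                                 rule = "any_positive", tau = 0) {
  stopifnot(length(subject_id) == length(score),
            length(slice_index) == length(score))
  out <- lapply(split(seq_along(score), subject_id), function(ix) {
    ix <- ix[order(slice_index[ix])]
    raw <- as.integer(score[ix] > threshold)
    filt <- as.integer(median_filter_1d(raw, filter_size))
    diag <- subject_decision(filt, rule, tau)
    data.frame(subject_id = subject_id[ix], slice_index = slice_index[ix],
               score = score[ix], raw = raw, filtered = filt,
               subject_diagnosis = diag, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
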