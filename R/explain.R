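#' Grad-CAM saliency map for a slice patch
#'
#' Computes the gradient-weighted class activation map over the last
#' convolutional stage of the classifier: the gradient of the target-class
#' logit with respect to the final convolutional feature maps is spatially
#' averaged to give one weight per channel; the map is the rectified
#' (negatives zeroed) weighted sum of the feature maps, bilinearly upsampled
#' to the patch size and normalized by its maximum.
#'
#' @param classifier a trained `bme_classifier`.
#' @param patch numeric matrix (or `roi_patch`) at the classifier input size.
#' @param target_class `"positive"` (default) or `"negative"`.
#' @return Object of class `saliency_map`: list with `map` (matrix in
#'   `[0,1]`, same size as the patch; all-zero when no positive evidence),
#'   `raw` (un-normalized low-resolution map), `weights` (per-channel
#'   gradient weights) and `target_class`.
#' @export
grad_cam <- function(classifier, patch, target_class = c("positive", "negative")) {
  stopifnot(inherits(classifier, "bme_classifier"))
  target_class <- match.arg(target_class)
  if (is.null(classifier$cam_index) || classifier$cam_index < 1L)
    stop("classifier has no convolutional feature maps")
  cfg <- classifier$config
  if (inherits(patch, "roi_patch")) patch <- patch$image
  arr <- apply_norm(classifier,
                    as_input_array(list(patch), cfg$input_size,
                                   classifier$in_channels))
  fw <- nn_forward(classifier$layers, arr, train = FALSE,
                   keep_output_of = classifier$cam_index)
  # gradient of the target-class logit
  dz <- matrix(0, nrow(fw$out), 1)
  node <- if (cfg$output_mode == "two_node") {
    if (target_class == "positive") 2L else 1L
  } else 1L
  sign <- if (cfg$output_mode == "single_logit" && target_class == "negative")
    -1 else 1
  dz[node, 1] <- sign
  bw <- nn_backward(classifier$layers, fw$caches, dz,
                    upto = classifier$cam_index)
  feats <- fw$kept          # (h, w, C, 1)
  grads <- bw$dx            # same shape
  d <- dim(feats)
  w <- apply(grads[, , , 1, drop = FALSE], 3, mean)  # channel weights
  raw <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) raw <- raw + w[c] * feats[, , c, 1]
  raw <- pmax(raw, 0)
  up <- cpp_resize_bilinear(raw, nrow(patch), ncol(patch))
  up <- pmax(up, 0)
  mx <- max(up)
  map <- if (mx > 0) up / mx else up
  structure(list(map = map, raw = raw, weights = w,
                 target_class = target_class),
            class = "saliency_map")
}

#' Render a saliency overlay
#'
#' Alpha-blends the color-mapped heatmap over the grayscale patch. The
#' colormap runs (coldest to hottest) blue, green, yellow, orange, red.
#'
#' @param map a `saliency_map` (or plain matrix in `[0,1]`).
#' @param patch grayscale matrix of the same size.
#' @param alpha maximum blend weight of the heatmap (default 0.5); each
#'   pixel's blend weight scales with its activation so weak regions keep
#'   the underlying anatomy visible.
#' @param file optional path; when given, the overlay is written as PNG.
#' @return `(rows, cols, 3)` RGB array in `[0,1]`, invisibly when written to
#'   file.
#' @export
overlay <- function(map, patch, alpha = 0.5, file = NULL) {
  m <- if (inherits(map, "saliency_map")) map$map else map
  if (!all(dim(m) == dim(patch))) stop("map and patch sizes differ")
  ramp <- grDevices::colorRamp(c("blue", "green", "yellow", "orange", "red"))
  cols <- ramp(as.vector(m)) / 255
  out <- array(0, c(nrow(m), ncol(m), 3))
  w <- alpha * as.vector(m)
  for (ch in 1:3)
    out[, , ch] <- matrix((1 - w) * as.vector(patch) + w * cols[, ch],
                          nrow(m), ncol(m))
  out <- pmin(pmax(out, 0), 1)
  if (!is.null(file)) {
    png::writePNG(out, file)
    return(invisible(out))
  }
  out
}
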