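#' Focal loss
#'
#' Cross-entropy variant that down-weights well-classified examples,
#' `FL(p) = -alpha * (1 - p)^gamma * log(p)`, where `p` is the predicted
#' probability of the true class. With `alpha = 1, gamma = 0` it reduces
#' exactly to the binary cross-entropy. Batch losses are the mean of the
#' per-sample values.
#'
#' @param p predicted probability (vector allowed) of the true class.
#' @param alpha class-balance weight in `(0, 1]` (default 0.25).
#' @param gamma focusing exponent, `>= 0` (default 2).
#' @param eps probabilities are clamped below at `eps` (default 1e-7).
#' @return Elementwise loss values (same length as `p`).
#' @examples
#' focal_loss(0.5, alpha = 1, gamma = 0)  # log(2)
#' focal_loss(0.9)                        # 0.25 * 0.01 * -log(0.9)
#' @export
focal_loss <- function(p, alpha = 0.25, gamma = 2, eps = 1e-7) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (gamma < 0) stop("gamma must be >= 0")
  p <- pmin(pmax(p, eps), 1)
  -alpha * (1 - p)^gamma * log(p)
}

# Loss and logits gradient for a batch. z: (K, N) logits; targets: (K, N)
# 0/1 per-node targets. Per-sample loss sums the node terms; the batch loss
# is the mean over samples.
focal_loss_grad <- function(z, targets, alpha, gamma, eps = 1e-7) {
  n <- ncol(z)
  q <- stats::plogis(z)
  p <- q * targets + (1 - q) * (1 - targets)
  pc <- pmin(pmax(p, eps), 1 - 1e-12)
  loss <- sum(-alpha * (1 - pc)^gamma * log(pc)) / n
  # d/dp of -alpha (1-p)^gamma log p
  dldp <- alpha * (1 - pc)^(gamma - 1) * (gamma * log(pc) - (1 - pc) / pc)
  dz <- dldp * (2 * targets - 1) * q * (1 - q) / n
  list(loss = loss, dz = dz)
}

#' Cosine learning-rate decay
#'
#' `lr(t) = lr_min + (lr0 - lr_min) * (1 + cos(pi * t / total)) / 2` for
#' `t = 0, ..., total`; the schedule starts at `lr0` and decays to `lr_min`.
#'
#' @param t epoch index (0-based; vector allowed), `0 <= t <= total`.
#' @param total total number of epochs, `>= 1`.
#' @param lr0 initial learning rate (default 0.03).
#' @param lr_min final learning rate (default 0).
#' @return Learning rate(s).
#' @export
cosine_lr <- function(t, total, lr0 = 0.03, lr_min = 0) {
  if (total < 1) stop("total must be >= 1")
  if (any(t < 0) || any(t > total)) stop("t must satisfy 0 <= t <= total")
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * t / total))
}

#' Slice-classifier configuration
#'
#' @param backbone `"tiny"` (3 conv blocks; the CPU-friendly choice for small
#'   synthetic experiments), `"resnet18"` (5-stage residual network, basic
#'   blocks) or `"resnet50"` (bottleneck blocks from the third stage).
#' @param pretrained initialize the backbone from a weights file (transfer
#'   learning). ImageNet weights are not bundled; supply `weights_file`.
#' @param weights_file optional RDS file with layer weights to load.
#' @param input_size classifier input `c(rows, cols)`; defaults to 224x224
#'   for the residual backbones and 64x64 for `"tiny"`.
#' @param output_mode `"two_node"` (two sigmoid output nodes, one per class)
#'   or `"single_logit"` (one sigmoid node for the positive class).
#' @param hidden_units width of the single hidden fully connected layer.
#' @param batch_size minibatch size (default 32).
#' @param initial_lr initial learning rate of the cosine schedule
#'   (default 0.03).
#' @param lr_min final learning rate of the schedule (default 0).
#' @param epochs training epochs (default 50).
#' @param focal_alpha,focal_gamma focal-loss parameters (defaults 0.25 / 2).
#' @param momentum SGD momentum (default 0.9).
#' @param augment apply horizontal-flip/rotation augmentation during training.
#' @param flip_prob,angle_range augmentation parameters (see [augment()]).
#' @param threshold decision threshold on the positive-class score
#'   (default 0.5).
#' @param seed integer seed controlling weight initialization, shuffling and
#'   augmentation.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(backbone = c("tiny", "resnet18", "resnet50"),
                              pretrained = FALSE, weights_file = NULL,
                              input_size = NULL,
                              output_mode = c("two_node", "single_logit"),
                              hidden_units = 64L, batch_size = 32L,
                              initial_lr = 0.03, lr_min = 0, epochs = 50L,
                              focal_alpha = 0.25, focal_gamma = 2,
                              momentum = 0.9, augment = TRUE,
                              flip_prob = 0.5, angle_range = 15,
                              threshold = 0.5, seed = 1L) {
  backbone <- match.arg(backbone)
  output_mode <- match.arg(output_mode)
  if (is.null(input_size))
    input_size <- if (backbone == "tiny") c(64L, 64L) else c(224L, 224L)
  cfg <- list(backbone = backbone, pretrained = pretrained,
              weights_file = weights_file,
              input_size = as.integer(input_size), output_mode = output_mode,
              hidden_units = as.integer(hidden_units),
              batch_size = as.integer(batch_size),
              initial_lr = initial_lr, lr_min = lr_min,
              epochs = as.integer(epochs),
              focal_alpha = focal_alpha, focal_gamma = focal_gamma,
              momentum = momentum, augment = augment, flip_prob = flip_prob,
              angle_range = angle_range, threshold = threshold,
              seed = as.integer(seed))
  if (cfg$batch_size < 1L) stop("batch_size must be >= 1")
  if (cfg$initial_lr <= 0) stop("initial_lr must be > 0")
  if (cfg$focal_gamma < 0) stop("focal_gamma must be >= 0")
  if (cfg$focal_alpha <= 0 || cfg$focal_alpha > 1)
    stop("focal_alpha must be in (0, 1]")
  if (cfg$epochs < 1L) stop("epochs must be >= 1")
  if (any(cfg$input_size %% 8L != 0L))
    stop("input_size must be divisible by 8")
  structure(cfg, class = "classifier_config")
}

n_output_nodes <- function(config) {
  if (config$output_mode == "two_node") 2L else 1L
}

# Architecture builders. `cam` marks the top-level layer whose output feeds
# Grad-CAM (the last convolutional-stage activation).
build_layers <- function(config, in_channels = 1L) {
  nout <- n_output_nodes(config)
  hid <- config$hidden_units
  if (config$backbone == "tiny") {
    layers <- list(
      nn_conv(3L, 3L, in_channels, 8L, 1L, 1L), nn_bn(8L), nn_relu(),
      nn_maxpool(2L),
      nn_conv(3L, 3L, 8L, 16L, 1L, 1L), nn_bn(16L), nn_relu(),
      nn_maxpool(2L),
      nn_conv(3L, 3L, 16L, 32L, 1L, 1L), nn_bn(32L), nn_relu())
    cam <- length(layers)
    layers <- c(layers, list(nn_maxpool(2L), nn_gap(),
                             nn_dense(32L, hid), nn_relu(),
                             nn_dense(hid, nout)))
  } else if (config$backbone == "resnet18") {
    layers <- list(
      nn_conv(7L, 7L, in_channels, 64L, 2L, 3L), nn_bn(64L), nn_relu(),
      nn_maxpool(3L, 2L, 1L),
      nn_basic_block(64L, 64L), nn_basic_block(64L, 64L),
      nn_basic_block(64L, 128L, 2L), nn_basic_block(128L, 128L),
      nn_basic_block(128L, 256L, 2L), nn_basic_block(256L, 256L),
      nn_basic_block(256L, 512L, 2L), nn_basic_block(512L, 512L))
    cam <- length(layers)
    layers <- c(layers, list(nn_gap(), nn_dense(512L, hid), nn_relu(),
                             nn_dense(hid, nout)))
  } else {  # resnet50: basic blocks in stage 2, bottlenecks from stage 3 on
    layers <- list(
      nn_conv(7L, 7L, in_channels, 64L, 2L, 3L), nn_bn(64L), nn_relu(),
      nn_maxpool(3L, 2L, 1L),
      nn_basic_block(64L, 64L), nn_basic_block(64L, 64L),
      nn_bottleneck_block(64L, 128L, 2L), nn_bottleneck_block(512L, 128L),
      nn_bottleneck_block(512L, 128L), nn_bottleneck_block(512L, 128L),
      nn_bottleneck_block(512L, 256L, 2L), nn_bottleneck_block(1024L, 256L),
      nn_bottleneck_block(1024L, 256L), nn_bottleneck_block(1024L, 256L),
      nn_bottleneck_block(1024L, 256L), nn_bottleneck_block(1024L, 256L),
      nn_bottleneck_block(1024L, 512L, 2L), nn_bottleneck_block(2048L, 512L),
      nn_bottleneck_block(2048L, 512L))
    cam <- length(layers)
    layers <- c(layers, list(nn_gap(), nn_dense(2048L, hid), nn_relu(),
                             nn_dense(hid, nout)))
  }
  list(layers = layers, cam_index = cam)
}

#' Build the slice classifier
#'
#' Constructs the convolutional classifier described by the configuration:
#' a residual (or tiny convolutional) backbone, global average pooling, one
#' hidden fully connected layer and a sigmoid output (one node per class in
#' `"two_node"` mode). Weight initialization is deterministic for a fixed
#' `config$seed`.
#'
#' @param config a [classifier_config()].
#' @param in_channels number of input channels (grayscale: 1).
#' @return An object of class `bme_classifier` (untrained).
#' @export
build_classifier <- function(config, in_channels = 1L) {
  stopifnot(inherits(config, "classifier_config"))
  built <- with_seed(config$seed, build_layers(config, in_channels))
  clf <- structure(list(layers = built$layers, cam_index = built$cam_index,
                        config = config, in_channels = as.integer(in_channels),
                        n_weighted = count_weighted_layers(built$layers),
                        history = NULL),
                   class = "bme_classifier")
  if (isTRUE(config$pretrained)) {
    if (is.null(config$weights_file))
      stop("pretrained = TRUE requires a weights_file; ",
           "ImageNet weights are not bundled with the package")
    clf <- load_backbone_weights(clf, config$weights_file)
  }
  clf
}

# Replace layer parameters with shape-compatible entries from an RDS file
# holding a layer list saved by save_checkpoint().
load_backbone_weights <- function(classifier, path) {
  src <- readRDS(path)
  if (!is.null(src$layers)) src <- src$layers
  n <- min(length(src), length(classifier$layers))
  for (i in seq_len(n)) {
    dst <- classifier$layers[[i]]
    cand <- src[[i]]
    if (!identical(dst$type, cand$type)) next
    for (nm in layer_param_names(dst)) {
      if (!is.null(cand[[nm]]) && identical(dim(cand[[nm]]), dim(dst[[nm]])) &&
          length(cand[[nm]]) == length(dst[[nm]]))
        dst[[nm]] <- cand[[nm]]
    }
    classifier$layers[[i]] <- dst
  }
  classifier
}

#' @export
print.bme_classifier <- function(x, ...) {
  cat(sprintf("<bme_classifier %s: %d weighted layers, input %dx%d, %s%s>\n",
              x$config$backbone, x$n_weighted,
              x$config$input_size[1], x$config$input_size[2],
              x$config$output_mode,
              if (is.null(x$history)) ", untrained" else ", trained"))
  invisible(x)
}

as_input_array <- function(x, input_size, in_channels = 1L) {
  if (is.list(x)) {
    n <- length(x)
    arr <- array(0, c(input_size[1], input_size[2], in_channels, n))
    for (i in seq_len(n)) {
      m <- x[[i]]
      if (inherits(m, "roi_patch")) m <- m$image
      if (!all(dim(m) == input_size))
        stop(sprintf("patch %d is %dx%d, classifier expects %dx%d",
                     i, nrow(m), ncol(m), input_size[1], input_size[2]))
      for (c in seq_len(in_channels)) arr[, , c, i] <- m
    }
    arr
  } else if (length(dim(x)) == 4L) {
    if (!all(dim(x)[1:2] == input_size)) stop("input array size mismatch")
    x
  } else stop("x must be a list of matrices or a 4-D array")
}

# Per-dataset standardization: statistics estimated from the training set at
# train time, stored on the classifier, and applied to every later input.
apply_norm <- function(classifier, arr) {
  if (is.null(classifier$norm)) return(arr)
  (arr - classifier$norm$mean) / classifier$norm$sd
}

make_targets <- function(y, output_mode) {
  if (output_mode == "two_node") rbind(1 - y, y) else matrix(y, nrow = 1)
}

scores_from_logits <- function(z, output_mode) {
  q <- stats::plogis(z)
  if (output_mode == "two_node") q[2, ] else q[1, ]
}

#' Train the slice classifier
#'
#' Minibatch SGD with momentum under the focal loss, batch normalization,
#' per-epoch cosine learning-rate decay starting at `config$initial_lr`, and
#' horizontal-flip/rotation augmentation. Training is deterministic for a
#' fixed `config$seed` under single-threaded execution.
#'
#' @param classifier an untrained (or previously trained) `bme_classifier`.
#' @param x training patches: list of matrices at the configured input size.
#' @param y integer slice labels (1 = lesion present, 0 = absent).
#' @param val_x,val_y optional validation set, evaluated once per epoch.
#' @param epochs number of epochs; defaults to `config$epochs`.
#' @param verbose print one line per epoch.
#' @return The trained classifier; `$history` is a data.frame with one row
#'   per epoch (`epoch`, `lr`, `train_loss`, `train_acc`, `val_acc`).
#' @export
train_classifier <- function(classifier, x, y, val_x = NULL, val_y = NULL,
                             epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(classifier, "bme_classifier"))
  cfg <- classifier$config
  if (is.null(epochs)) epochs <- cfg$epochs
  y <- as.integer(y)
  if (length(y) == 0L) stop("empty training set")
  if (length(unique(y)) < 2L)
    warning("training set contains a single class; proceeding (focal loss ",
            "is designed for imbalance, but learning both classes needs both)")
  xs <- if (is.list(x)) lapply(x, function(m) if (inherits(m, "roi_patch")) m$image else m)
        else stop("x must be a list of patch matrices")
  n <- length(xs)
  if (n != length(y)) stop("x and y lengths differ")
  # per-dataset intensity standardization (computed once from training data)
  mu <- mean(vapply(xs, mean, numeric(1)))
  m2 <- mean(vapply(xs, function(m) mean(m * m), numeric(1)))
  classifier$norm <- list(mean = mu, sd = max(sqrt(max(m2 - mu^2, 0)), 1e-8))
  layers <- classifier$layers
  vel <- zero_like_grads(layers)
  hist <- data.frame(epoch = integer(0), lr = numeric(0),
                     train_loss = numeric(0), train_acc = numeric(0),
                     val_acc = numeric(0))
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      lr <- cosine_lr(ep - 1L, epochs, cfg$initial_lr, cfg$lr_min)
      ord <- sample.int(n)
      losses <- c(); correct <- 0L
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        xb <- xs[idx]
        if (isTRUE(cfg$augment))
          xb <- lapply(xb, augment, flip_prob = cfg$flip_prob,
                       angle_range = cfg$angle_range)
        arr <- apply_norm(classifier,
                          as_input_array(xb, cfg$input_size,
                                         classifier$in_channels))
        fw <- nn_forward(layers, arr, train = TRUE)
        layers <- fw$layers
        targets <- make_targets(y[idx], cfg$output_mode)
        lg <- focal_loss_grad(fw$out, targets, cfg$focal_alpha,
                              cfg$focal_gamma)
        losses <- c(losses, lg$loss)
        sc <- scores_from_logits(fw$out, cfg$output_mode)
        correct <- correct + sum((sc > cfg$threshold) == (y[idx] == 1L))
        bw <- nn_backward(layers, fw$caches, lg$dz)
        up <- sgd_update(layers, bw$grads, vel, lr, cfg$momentum)
        layers <- up$layers; vel <- up$vel
      }
      classifier$layers <- layers
      vacc <- NA_real_
      if (!is.null(val_x) && length(val_x) > 0) {
        vs <- predict_slices(classifier, val_x)
        vacc <- mean((vs > cfg$threshold) == (as.integer(val_y) == 1L))
      }
      hist <- rbind(hist, data.frame(epoch = ep, lr = lr,
                                     train_loss = mean(losses),
                                     train_acc = correct / n, val_acc = vacc))
      if (verbose)
        message(sprintf("epoch %3d  lr %.5f  loss %.4f  acc %.3f  val %.3f",
                        ep, lr, mean(losses), correct / n, vacc))
    }
  })
  # Recalibrate batch-norm running statistics on the un-augmented training
  # data: with momentum 1/k over batches k = 1..K the running statistics end
  # up as the average per-batch statistics, matching what the network sees
  # at evaluation time (augmented batches bias them otherwise).
  k <- 0L
  for (b0 in seq(1L, n, by = cfg$batch_size)) {
    k <- k + 1L
    layers <- bn_set_momentum(layers, 1 / k)
    idx <- b0:min(b0 + cfg$batch_size - 1L, n)
    arr <- apply_norm(classifier,
                      as_input_array(xs[idx], cfg$input_size,
                                     classifier$in_channels))
    layers <- nn_forward(layers, arr, train = TRUE)$layers
  }
  layers <- bn_set_momentum(layers, 0.1)
  classifier$layers <- layers
  classifier$history <- hist
  classifier
}

#' Predict the BME-positive probability for one slice patch
#'
#' @param classifier a `bme_classifier`.
#' @param patch numeric matrix (or `roi_patch`) at the configured input size.
#' @return Score in `[0,1]`; the binary decision is `score > threshold`
#'   (threshold 0.5 by default).
#' @export
predict_slice <- function(classifier, patch) {
  predict_slices(classifier, list(patch))[1]
}

#' Predict scores for many patches
#'
#' @param classifier a `bme_classifier`.
#' @param patches list of matrices (or `roi_patch` objects).
#' @param batch_size forward-pass chunk size.
#' @return Numeric vector of positive-class scores in `[0,1]`.
#' @export
predict_slices <- function(classifier, patches, batch_size = 64L) {
  stopifnot(inherits(classifier, "bme_classifier"))
  cfg <- classifier$config
  n <- length(patches)
  out <- numeric(n)
  for (b0 in seq(1L, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, n)
    arr <- apply_norm(classifier,
                      as_input_array(patches[idx], cfg$input_size,
                                     classifier$in_channels))
    fw <- nn_forward(classifier$layers, arr, train = FALSE)
    out[idx] <- scores_from_logits(fw$out, cfg$output_mode)
  }
  out
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint holds the configuration, all layer weights (including
#' batch-norm running statistics) and the training history.
#'
#' @param classifier a `bme_classifier`.
#' @param path file path.
#' @return `load_checkpoint` returns the classifier.
#' @export
save_checkpoint <- function(classifier, path) {
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "bme_classifier"))
  obj
}
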