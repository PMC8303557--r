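# Minimal CNN engine used by the slice classifier.
#
# Feature maps are R arrays (H, W, C, N); dense activations are matrices
# (features, N). Layers are plain lists with a $type; residual blocks nest a
# main path and an optional projection shortcut. Everything is deterministic
# given the R RNG state (weight init, shuffling, augmentation all draw from
# it) and single-threaded.

nn_conv <- function(kh, kw, cin, cout, stride = 1L, pad = 0L) {
  sd <- sqrt(2 / (kh * kw * cin))  # He initialization
  list(type = "conv",
       w = array(rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout)),
       b = numeric(cout), stride = as.integer(stride), pad = as.integer(pad))
}

nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c), momentum = momentum, eps = eps)
}

nn_relu <- function() list(type = "relu")

nn_maxpool <- function(size = 2L, stride = size, pad = 0L) {
  list(type = "maxpool", size = as.integer(size), stride = as.integer(stride),
       pad = as.integer(pad))
}

nn_gap <- function() list(type = "gap")

nn_dense <- function(cin, cout) {
  list(type = "dense", w = matrix(rnorm(cout * cin, 0, sqrt(2 / cin)), cout, cin),
       b = numeric(cout))
}

nn_block <- function(main, shortcut = NULL) {
  list(type = "block", main = main, shortcut = shortcut)
}

# Standard two-conv residual block; projection shortcut when the shape changes.
nn_basic_block <- function(cin, cout, stride = 1L) {
  main <- list(nn_conv(3L, 3L, cin, cout, stride, 1L), nn_bn(cout), nn_relu(),
               nn_conv(3L, 3L, cout, cout, 1L, 1L), nn_bn(cout))
  shortcut <- if (stride != 1L || cin != cout)
    list(nn_conv(1L, 1L, cin, cout, stride, 0L), nn_bn(cout)) else NULL
  nn_block(main, shortcut)
}

# 1x1 -> 3x3 -> 1x1 bottleneck block with expansion 4.
nn_bottleneck_block <- function(cin, mid, stride = 1L) {
  cout <- 4L * mid
  main <- list(nn_conv(1L, 1L, cin, mid, 1L, 0L), nn_bn(mid), nn_relu(),
               nn_conv(3L, 3L, mid, mid, stride, 1L), nn_bn(mid), nn_relu(),
               nn_conv(1L, 1L, mid, cout, 1L, 0L), nn_bn(cout))
  shortcut <- if (stride != 1L || cin != cout)
    list(nn_conv(1L, 1L, cin, cout, stride, 0L), nn_bn(cout)) else NULL
  nn_block(main, shortcut)
}

layer_forward <- function(layer, x, train) {
  switch(layer$type,
    conv = {
      y <- cpp_conv2d_fwd(x, layer$w, layer$b, layer$stride, layer$pad)
      list(y = y, cache = list(x = x), layer = layer)
    },
    bn = {
      d <- dim(x); m <- d[1] * d[2] * d[4]
      xp <- aperm(x, c(1, 2, 4, 3)); dim(xp) <- c(m, d[3])
      if (train) {
        mu <- colMeans(xp)
        v <- colMeans(xp * xp) - mu * mu
        layer$rmean <- (1 - layer$momentum) * layer$rmean + layer$momentum * mu
        layer$rvar <- (1 - layer$momentum) * layer$rvar + layer$momentum * v
      } else {
        mu <- layer$rmean; v <- layer$rvar
      }
      sdv <- sqrt(v + layer$eps)
      xh <- sweep(sweep(xp, 2, mu, "-"), 2, sdv, "/")
      yp <- sweep(sweep(xh, 2, layer$gamma, "*"), 2, layer$beta, "+")
      dim(yp) <- c(d[1], d[2], d[4], d[3])
      list(y = aperm(yp, c(1, 2, 4, 3)),
           cache = list(xh = xh, sdv = sdv, d = d), layer = layer)
    },
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = list(mask = mask), layer = layer)
    },
    maxpool = {
      r <- cpp_maxpool_fwd(x, layer$size, layer$stride, layer$pad)
      list(y = r$y, cache = list(idx = r$idx, xdim = dim(x)), layer = layer)
    },
    gap = {
      d <- dim(x)
      m <- matrix(x, nrow = d[1] * d[2])
      y <- array(colMeans(m), c(1L, 1L, d[3], d[4]))
      list(y = y, cache = list(d = d), layer = layer)
    },
    dense = {
      xdim <- dim(x)
      n <- xdim[length(xdim)]
      xf <- matrix(x, ncol = n)
      y <- layer$w %*% xf + layer$b
      list(y = y, cache = list(xf = xf, xdim = xdim), layer = layer)
    },
    block = {
      h <- x
      mc <- vector("list", length(layer$main))
      for (i in seq_along(layer$main)) {
        fr <- layer_forward(layer$main[[i]], h, train)
        layer$main[[i]] <- fr$layer; mc[[i]] <- fr$cache; h <- fr$y
      }
      if (is.null(layer$shortcut)) {
        s <- x; sc <- NULL
      } else {
        s <- x
        sc <- vector("list", length(layer$shortcut))
        for (i in seq_along(layer$shortcut)) {
          fr <- layer_forward(layer$shortcut[[i]], s, train)
          layer$shortcut[[i]] <- fr$layer; sc[[i]] <- fr$cache; s <- fr$y
        }
      }
      z <- h + s
      mask <- z > 0
      list(y = z * mask, cache = list(main = mc, shortcut = sc, mask = mask),
           layer = layer)
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- cpp_conv2d_bwd(cache$x, layer$w, dy, layer$stride, layer$pad)
      list(dx = g$dx, grads = list(w = g$dw, b = g$db))
    },
    bn = {
      d <- cache$d; m <- d[1] * d[2] * d[4]
      dyp <- aperm(dy, c(1, 2, 4, 3)); dim(dyp) <- c(m, d[3])
      dgamma <- colSums(dyp * cache$xh)
      dbeta <- colSums(dyp)
      dxh <- sweep(dyp, 2, layer$gamma, "*")
      t1 <- sweep(dxh, 2, colMeans(dxh), "-")
      t2 <- sweep(cache$xh, 2, colMeans(dxh * cache$xh), "*")
      dxp <- sweep(t1 - t2, 2, cache$sdv, "/")
      dim(dxp) <- c(d[1], d[2], d[4], d[3])
      list(dx = aperm(dxp, c(1, 2, 4, 3)),
           grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dy * cache$mask, grads = NULL),
    maxpool = list(dx = cpp_maxpool_bwd(cache$idx, dy, cache$xdim), grads = NULL),
    gap = {
      d <- cache$d
      per <- as.vector(dy) / (d[1] * d[2])
      list(dx = array(rep(per, each = d[1] * d[2]), d), grads = NULL)
    },
    dense = {
      dw <- dy %*% t(cache$xf)
      db <- rowSums(dy)
      dxf <- t(layer$w) %*% dy
      dx <- dxf; dim(dx) <- cache$xdim
      list(dx = dx, grads = list(w = dw, b = db))
    },
    block = {
      dz <- dy * cache$mask
      dh <- dz
      gmain <- vector("list", length(layer$main))
      for (i in rev(seq_along(layer$main))) {
        bb <- layer_backward(layer$main[[i]], cache$main[[i]], dh)
        gmain[i] <- list(bb$grads); dh <- bb$dx
      }
      if (is.null(layer$shortcut)) {
        ds <- dz; gshort <- NULL
      } else {
        ds <- dz
        gshort <- vector("list", length(layer$shortcut))
        for (i in rev(seq_along(layer$shortcut))) {
          bb <- layer_backward(layer$shortcut[[i]], cache$shortcut[[i]], ds)
          gshort[i] <- list(bb$grads); ds <- bb$dx
        }
      }
      list(dx = dh + ds, grads = list(main = gmain, shortcut = gshort))
    },
    stop("unknown layer type: ", layer$type))
}

# Forward through the whole stack. Returns logits, per-layer caches (the
# cached activation entering layer i is reachable through caches[[i]]), the
# per-layer outputs for the Grad-CAM target layer, and layers with updated
# batch-norm running statistics.
nn_forward <- function(layers, x, train = FALSE, keep_output_of = 0L) {
  caches <- vector("list", length(layers))
  kept <- NULL
  for (i in seq_along(layers)) {
    fr <- layer_forward(layers[[i]], x, train)
    layers[[i]] <- fr$layer
    caches[[i]] <- fr$cache
    x <- fr$y
    if (i == keep_output_of) kept <- x
  }
  list(out = x, caches = caches, layers = layers, kept = kept)
}

# Backward from the logits gradient down to (and excluding) layer `upto`.
# Returns the gradient flowing out of layer upto+1 (i.e. w.r.t. the output of
# layer `upto`) and per-layer parameter gradients for the traversed layers.
nn_backward <- function(layers, caches, dy, upto = 0L) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (i <= upto) break
    bb <- layer_backward(layers[[i]], caches[[i]], dy)
    grads[i] <- list(bb$grads)  # [[<-]] with NULL would drop the slot
    dy <- bb$dx
  }
  list(dx = dy, grads = grads)
}

layer_param_names <- function(layer) {
  switch(layer$type,
    conv = c("w", "b"), bn = c("gamma", "beta"), dense = c("w", "b"),
    character(0))
}

zero_like_grads <- function(layers) {
  lapply(layers, function(l) {
    if (l$type == "block") {
      list(main = zero_like_grads(l$main),
           shortcut = if (is.null(l$shortcut)) NULL else zero_like_grads(l$shortcut))
    } else {
      nms <- layer_param_names(l)
      if (length(nms) == 0) NULL else {
        g <- lapply(nms, function(nm) l[[nm]] * 0)
        names(g) <- nms
        g
      }
    }
  })
}

sgd_update <- function(layers, grads, vel, lr, momentum) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]; g <- grads[[i]]
    if (is.null(g)) next
    if (l$type == "block") {
      up <- sgd_update(l$main, g$main, vel[[i]]$main, lr, momentum)
      l$main <- up$layers; vel[[i]]$main <- up$vel
      if (!is.null(l$shortcut)) {
        up <- sgd_update(l$shortcut, g$shortcut, vel[[i]]$shortcut, lr, momentum)
        l$shortcut <- up$layers; vel[[i]]$shortcut <- up$vel
      }
    } else {
      for (nm in layer_param_names(l)) {
        vel[[i]][[nm]] <- momentum * vel[[i]][[nm]] - lr * g[[nm]]
        l[[nm]] <- l[[nm]] + vel[[i]][[nm]]
      }
    }
    layers[[i]] <- l
  }
  list(layers = layers, vel = vel)
}

# Set the running-statistics momentum of every batch-norm layer.
# With momentum 1/k over batches k = 1..K the running statistics become the
# plain average of the per-batch statistics (used for post-training
# recalibration on un-augmented data).
bn_set_momentum <- function(layers, m) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "bn") l$momentum <- m
    if (l$type == "block") {
      l$main <- bn_set_momentum(l$main, m)
      if (!is.null(l$shortcut)) l$shortcut <- bn_set_momentum(l$shortcut, m)
    }
    layers[[i]] <- l
  }
  layers
}

# Count weighted layers the way ResNet depths are conventionally quoted:
# convolutions on the main paths (projection shortcuts excluded) plus the
# final classification layer.
count_weighted_layers <- function(layers) {
  count_convs <- function(ls) {
    n <- 0L
    for (l in ls) {
      if (l$type == "conv") n <- n + 1L
      if (l$type == "block") n <- n + count_convs(l$main)
    }
    n
  }
  count_convs(layers) + 1L
}
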