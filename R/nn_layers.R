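## A small, fully seeded layer framework sufficient for the phenotype
## classifier: conv / batchnorm / relu / maxpool / global-average-pool /
## dense layers plus residual blocks, with explicit forward and backward
## passes over (H, W, C, N) arrays. Convolution and pooling kernels are
## compiled (src/nn_ops.cpp); everything else is plain R.
##
## Forward passes carry a `train` flag: batch normalization uses batch
## statistics (and updates its running averages) in training and the frozen
## running averages in evaluation. net_forward therefore returns the
## possibly-updated layers along with the output and caches.

nn_conv <- function(cin, cout, k, stride = 1L, pad = as.integer(floor(k / 2))) {
  fan_in <- k * k * cin
  W <- array(rnorm(k * k * cin * cout, 0, sqrt(2 / fan_in)),
             dim = c(k, k, cin, cout))
  list(type = "conv", W = W, b = numeric(cout),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad))
}

## per-channel batch normalization; W = gamma, b = beta so the parameter
## tree treats it like any other weighted layer
nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", W = rep(1, c), b = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c),
       momentum = momentum, eps = eps)
}

nn_relu <- function() list(type = "relu")

nn_maxpool <- function(k = 2L, stride = k, pad = 0L)
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))

nn_gap <- function() list(type = "gap")

## near-zero head init: an untrained classifier should emit ~uniform softmax
nn_dense <- function(cin, cout) {
  list(type = "dense",
       W = matrix(rnorm(cout * cin, 0, 0.01), cout, cin),
       b = numeric(cout))
}

## main and shortcut are layer lists; shortcut NULL means identity
nn_residual <- function(main, shortcut = NULL)
  list(type = "residual", main = main, shortcut = shortcut)


layer_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    conv = {
      y <- conv2d_fwd(x, layer$W, layer$b, layer$stride, layer$pad)
      list(out = y, cache = x, layer = layer)
    },
    bn = {
      r <- bn_fwd(x, layer$W, layer$b, layer$run_mean, layer$run_var,
                  train, layer$momentum, layer$eps)
      layer$run_mean <- r$run_mean
      layer$run_var <- r$run_var
      list(out = r$y,
           cache = list(xhat = r$xhat, invstd = r$invstd, train = train),
           layer = layer)
    },
    relu = {
      m <- x > 0
      list(out = x * m, cache = m, layer = layer)
    },
    maxpool = {
      r <- maxpool_fwd(x, layer$k, layer$stride, layer$pad)
      list(out = r$y, cache = list(idx = r$idx, H = dim(x)[1L],
                                   W = dim(x)[2L]), layer = layer)
    },
    gap = {
      d <- dim(x)
      hw <- d[1L] * d[2L]
      y <- matrix(.colMeans(x, hw, d[3L] * d[4L]), d[3L], d[4L])
      list(out = y, cache = d, layer = layer)
    },
    dense = {
      list(out = layer$W %*% x + layer$b, cache = x, layer = layer)
    },
    residual = {
      fm <- net_forward(layer$main, x, train)
      layer$main <- fm$layers
      if (is.null(layer$shortcut)) {
        s_out <- x; s_cache <- NULL
      } else {
        fs <- net_forward(layer$shortcut, x, train)
        layer$shortcut <- fs$layers
        s_out <- fs$out; s_cache <- fs$caches
      }
      pre <- fm$out + s_out
      m <- pre > 0
      list(out = pre * m,
           cache = list(main = fm$caches, shortcut = s_cache, relu = m),
           layer = layer)
    },
    stop("unknown layer type ", layer$type))
}

layer_backward <- function(layer, cache, g) {
  switch(layer$type,
    conv = {
      r <- conv2d_bwd(cache, layer$W, g, layer$stride, layer$pad)
      list(gx = r$gx, grads = list(W = r$gw, b = as.numeric(r$gb)))
    },
    bn = {
      r <- bn_bwd(g, cache$xhat, cache$invstd, layer$W, cache$train)
      list(gx = r$gx,
           grads = list(W = as.numeric(r$dgamma), b = as.numeric(r$dbeta)))
    },
    relu = list(gx = g * cache, grads = NULL),
    maxpool = list(gx = maxpool_bwd(g, cache$idx, cache$H, cache$W),
                   grads = NULL),
    gap = {
      d <- cache
      npix <- d[1L] * d[2L]
      gx <- array(rep(as.vector(g) / npix, each = npix), dim = d)
      list(gx = gx, grads = NULL)
    },
    dense = {
      list(gx = crossprod(layer$W, g),
           grads = list(W = tcrossprod(g, cache), b = rowSums(g)))
    },
    residual = {
      gpre <- g * cache$relu
      bm <- net_backward(layer$main, cache$main, gpre)
      if (is.null(layer$shortcut)) {
        gx <- bm$gx + gpre
        gs <- NULL
      } else {
        bs <- net_backward(layer$shortcut, cache$shortcut, gpre)
        gx <- bm$gx + bs$gx
        gs <- bs$grads
      }
      list(gx = gx, grads = list(main = bm$grads, shortcut = gs))
    },
    stop("unknown layer type ", layer$type))
}

net_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train)
    x <- r$out
    caches[i] <- list(r$cache)
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, g) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], g)
    g <- r$gx
    grads[i] <- list(r$grads)  # [[<- would drop NULL entries
  }
  list(gx = g, grads = grads)
}

## apply f to every batch-norm layer, recursing into residual blocks
bn_apply <- function(layers, f) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "bn") layers[[i]] <- f(l)
    else if (l$type == "residual") {
      layers[[i]]$main <- bn_apply(l$main, f)
      if (!is.null(l$shortcut))
        layers[[i]]$shortcut <- bn_apply(l$shortcut, f)
    }
  }
  layers
}

## Recompute batch-norm running statistics as the exact average of batch
## statistics over a dataset (one forward pass, no augmentation). During
## training the exponential running averages lag the fast-moving weights;
## at desk-scale step counts that lag visibly distorts evaluation-mode
## outputs, so the final model's statistics are recalibrated.
bn_recalibrate <- function(layers, x, batch_size = 32L) {
  layers <- bn_apply(layers, function(l) {
    l$run_mean[] <- 0; l$run_var[] <- 0; l
  })
  n <- dim(x)[4L]
  nb <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    nb <- nb + 1L
    layers <- bn_apply(layers, function(l) { l$momentum <- 1 / nb; l })
    sel <- start:min(start + batch_size - 1L, n)
    layers <- net_forward(layers, x[, , , sel, drop = FALSE],
                          train = TRUE)$layers
  }
  bn_apply(layers, function(l) { l$momentum <- 0.1; l })
}

## ---- parameter trees ------------------------------------------------------
## Parameters live inside the layer list; these walk layers and a parallel
## gradient tree so one optimizer works for plain chains and nested blocks.

net_params <- function(layers) {
  lapply(layers, function(l) {
    switch(l$type,
      conv = , dense = , bn = list(W = l$W, b = l$b),
      residual = list(main = net_params(l$main),
                      shortcut = if (is.null(l$shortcut)) NULL
                                 else net_params(l$shortcut)),
      NULL)
  })
}

net_set_params <- function(layers, params) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type %in% c("conv", "dense", "bn")) {
      layers[[i]]$W <- params[[i]]$W
      layers[[i]]$b <- params[[i]]$b
    } else if (l$type == "residual") {
      layers[[i]]$main <- net_set_params(l$main, params[[i]]$main)
      if (!is.null(l$shortcut))
        layers[[i]]$shortcut <- net_set_params(l$shortcut,
                                               params[[i]]$shortcut)
    }
  }
  layers
}

tree_map2 <- function(a, b, f) {
  if (is.null(a)) return(NULL)
  if (is.numeric(a)) return(f(a, b))
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (i in seq_along(a)) out[i] <- list(tree_map2(a[[i]], b[[i]], f))
  out
}

tree_zero <- function(a) tree_map2(a, a, function(x, y) x * 0)

## ---- ADAM -----------------------------------------------------------------

adam_init <- function(params)
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v,
                   function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- tree_map2(params, upd, `-`)
  list(params = params, state = state)
}

## ---- losses ---------------------------------------------------------------

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

## logits (n_classes x N), labels in 1..n_classes
cross_entropy <- function(logits, labels) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  picked <- p[cbind(labels, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  g <- p
  g[cbind(labels, seq_len(n))] <- g[cbind(labels, seq_len(n))] - 1
  list(loss = loss, grad = g / n, probs = p)
}

## ---- architectures --------------------------------------------------------

#' Build the classifier network
#'
#' Both backbones take a single grayscale channel: a 3x3 convolution first
#' expands 1 channel to 3 (the "artificial RGB" adapter), then either a
#' compact 3-block CNN (`small_cnn`, the default — adequate for the binary
#' phenotype task at desk scale) or an 18-layer residual network
#' (`resnet18_like`: 7x7 stem, four stages of two basic blocks with channel
#' widths 64/128/256/512, batch-normalized, with 1x1 strided projection
#' shortcuts) feeds a global-average pool and a 2-unit output head whose
#' softmax gives the probability of each spheroid type.
#'
#' @param backbone `"small_cnn"` or `"resnet18_like"`.
#' @param n_classes number of output classes (2: round vs branched).
#' @return List of layers (used by [train_classifier()]).
#' @export
build_network <- function(backbone = c("small_cnn", "resnet18_like"),
                          n_classes = 2L) {
  backbone <- match.arg(backbone)
  if (backbone == "small_cnn") {
    block <- function(cin, cout)
      list(nn_conv(cin, cout, 3L), nn_bn(cout), nn_relu(), nn_maxpool(2L))
    c(list(nn_conv(1L, 3L, 3L)),           # 1 -> 3 channel adapter
      block(3L, 8L), block(8L, 16L), block(16L, 32L),
      list(nn_gap(), nn_dense(32L, n_classes)))
  } else {
    basic_block <- function(cin, cout, stride) {
      nn_residual(
        main = list(nn_conv(cin, cout, 3L, stride = stride), nn_bn(cout),
                    nn_relu(), nn_conv(cout, cout, 3L), nn_bn(cout)),
        shortcut = if (stride != 1L || cin != cout)
          list(nn_conv(cin, cout, 1L, stride = stride, pad = 0L),
               nn_bn(cout))
        else NULL)
    }
    stage <- function(cin, cout, stride)
      list(basic_block(cin, cout, stride), basic_block(cout, cout, 1L))
    c(list(nn_conv(1L, 3L, 3L),
           nn_conv(3L, 64L, 7L, stride = 2L, pad = 3L), nn_bn(64L),
           nn_relu(), nn_maxpool(3L, stride = 2L, pad = 1L)),
      stage(64L, 64L, 1L), stage(64L, 128L, 2L),
      stage(128L, 256L, 2L), stage(256L, 512L, 2L),
      list(nn_gap(), nn_dense(512L, n_classes)))
  }
}
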