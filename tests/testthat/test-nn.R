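# The compiled convolution/pooling kernels and the layer graph are checked
# two ways: against naive R reference implementations and against
# finite-difference gradients.

naive_conv <- function(x, w, b, stride, pad) {
  # x: (H,W,Cin), w: (k,k,Cin,Cout)
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, Cin))
  xp[pad + seq_len(H), pad + seq_len(W), ] <- x
  y <- array(0, c(Ho, Wo, Cout))
  for (o in seq_len(Cout)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    r0 <- (i - 1) * stride; c0 <- (j - 1) * stride
    y[i, j, o] <- sum(xp[r0 + seq_len(k), c0 + seq_len(k), ] *
                        w[, , , o]) + b[o]
  }
  y
}

test_that("compiled convolution matches the naive reference", {
  set.seed(2)
  for (cfg in list(c(3, 1, 1), c(3, 2, 1), c(1, 2, 0), c(7, 2, 3))) {
    k <- cfg[1]; s <- cfg[2]; p <- cfg[3]
    x <- array(rnorm(11 * 13 * 2 * 2), c(11, 13, 2, 2))
    w <- array(rnorm(k^2 * 2 * 3), c(k, k, 2, 3))
    b <- rnorm(3)
    y <- deltasphere:::conv2d_fwd(x, w, b, s, p)
    for (n in 1:2)
      expect_equal(y[, , , n], naive_conv(x[, , , n], w, b, s, p),
                   tolerance = 1e-12)
  }
})

test_that("maxpool matches a naive reference and routes gradients back", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  r <- deltasphere:::maxpool_fwd(x, 2L, 2L, 0L)
  for (n in 1:2) for (c in 1:2) for (i in 1:4) for (j in 1:4) {
    blk <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c, n]
    expect_equal(r$y[i, j, c, n], max(blk))
  }
  gy <- array(1, dim(r$y))
  gx <- deltasphere:::maxpool_bwd(gy, r$idx, 8L, 8L)
  expect_equal(sum(gx), sum(gy))           # each window routes one unit
  expect_true(all(gx %in% c(0, 1)))
  expect_true(all(gx[r$idx + 1L +
                       rep((0:3) * 64L, each = 16L)] == 1))
})

test_that("analytic gradients match finite differences for both backbones", {
  loss_of <- function(layers, x, labels)
    deltasphere:::cross_entropy(
      deltasphere:::net_forward(layers, x, train = TRUE)$out, labels)$loss
  fd_check <- function(backbone, hw, picks) {
    set.seed(10)
    x <- array(rnorm(hw * hw * 1 * 4), c(hw, hw, 1, 4))
    labels <- c(1L, 2L, 2L, 1L)
    layers <- build_network(backbone)
    fw <- deltasphere:::net_forward(layers, x, train = TRUE)
    ce <- deltasphere:::cross_entropy(fw$out, labels)
    bw <- deltasphere:::net_backward(fw$layers, fw$caches, ce$grad)
    eps <- 1e-6
    bump <- function(l2, p, delta) {
      if (is.null(p$sub)) l2[[p$i]]$W[p$idx] <- l2[[p$i]]$W[p$idx] + delta
      else if (p$sub == "main")
        l2[[p$i]]$main[[p$j]]$W[p$idx] <-
          l2[[p$i]]$main[[p$j]]$W[p$idx] + delta
      else l2[[p$i]]$shortcut[[p$j]]$W[p$idx] <-
          l2[[p$i]]$shortcut[[p$j]]$W[p$idx] + delta
      l2
    }
    pick_grad <- function(p) {
      if (is.null(p$sub)) bw$grads[[p$i]]$W[p$idx]
      else if (p$sub == "main") bw$grads[[p$i]]$main[[p$j]]$W[p$idx]
      else bw$grads[[p$i]]$shortcut[[p$j]]$W[p$idx]
    }
    for (p in picks) {
      g_num <- (loss_of(bump(layers, p, eps), x, labels) -
                  loss_of(bump(layers, p, -eps), x, labels)) / (2 * eps)
      # central differences; ReLU/maxpool kinks near the point leave ~1%
      # finite-difference noise in the deep net, far below a real defect
      expect_equal(pick_grad(p), g_num, tolerance = 2e-2)
    }
  }
  # small_cnn: adapter conv, conv, batchnorm gamma, deep conv, dense head
  fd_check("small_cnn", 16,
           list(list(i = 1L, idx = 5L), list(i = 2L, idx = 11L),
                list(i = 3L, idx = 2L), list(i = 10L, idx = 20L),
                list(i = 15L, idx = 2L)))
  # resnet: stem conv, stem batchnorm, block conv + bn, projection shortcut
  fd_check("resnet18_like", 32,
           list(list(i = 2L, idx = 9L), list(i = 3L, idx = 5L),
                list(i = 6L, sub = "main", j = 1L, idx = 3L),
                list(i = 6L, sub = "main", j = 2L, idx = 1L),
                list(i = 8L, sub = "shortcut", j = 1L, idx = 1L),
                list(i = 15L, idx = 1L)))
})

test_that("softmax cross-entropy behaves at the uninformed point", {
  z <- matrix(0, 2, 8)
  labels <- rep(1:2, 4)
  ce <- deltasphere:::cross_entropy(z, labels)
  expect_equal(ce$loss, log(2), tolerance = 1e-12)
  expect_true(all(abs(colSums(ce$probs) - 1) < 1e-12))
})

test_that("resnet18_like carries 18 weighted layers after the adapter", {
  layers <- build_network("resnet18_like")
  count <- function(ls) {
    n <- 0L
    for (l in ls) {
      if (l$type %in% c("conv", "dense")) n <- n + 1L
      if (l$type == "residual") n <- n + count(l$main)  # shortcuts excluded
    }
    n
  }
  expect_equal(count(layers) - 1L, 18L)   # minus the 1->3 adapter
})
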