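# Gradient correctness of the network engine against central finite
# differences.  Checks run at batch size 2: with a single sample, batch
# normalization makes channel means exactly zero, which parks the
# freshly-initialized cSE bottleneck exactly on its ReLU kink where finite
# differences are not informative.

ns <- asNamespace("msfaunet")

test_that("convolution kernels backpropagate exact gradients", {
  set.seed(42)
  x <- array(rnorm(3 * 6 * 6 * 2), c(3, 6, 6, 2))
  W <- matrix(rnorm(4 * 27) * 0.3, 4, 27)
  b <- rnorm(4) * 0.1
  for (stride in c(1L, 2L)) {
    y <- ns$.conv2d_fwd(x, W, b, 3L, stride, 1L)
    dy <- array(rnorm(length(y)), dim(y))
    g <- ns$.conv2d_bwd(x, W, dy, 3L, stride, 1L)
    loss <- function(x., W., b.) sum(ns$.conv2d_fwd(x., W., b., 3L, stride, 1L) * dy)
    for (i in sample(length(x), 4))
      expect_equal(fd_grad(function(v) loss(v, W, b), x, i), g$dx[i],
                   tolerance = 1e-5)
    for (i in sample(length(W), 4))
      expect_equal(fd_grad(function(v) loss(x, v, b), W, i), g$dW[i],
                   tolerance = 1e-5)
    expect_equal(fd_grad(function(v) loss(x, W, v), b, 2), g$db[2],
                 tolerance = 1e-5)
  }
})

test_that("transposed convolution doubles resolution and backpropagates", {
  set.seed(43)
  x <- array(rnorm(3 * 5 * 7 * 2), c(3, 5, 7, 2))
  W <- matrix(rnorm(3 * 4 * 9) * 0.3, 3, 36)
  b <- rnorm(4) * 0.1
  y <- ns$.convt2d_fwd(x, W, b, 3L, 2L, 1L)
  expect_equal(dim(y), c(4, 10, 14, 2))
  dy <- array(rnorm(length(y)), dim(y))
  g <- ns$.convt2d_bwd(x, W, dy, 3L, 2L, 1L)
  loss <- function(x., W., b.) sum(ns$.convt2d_fwd(x., W., b., 3L, 2L, 1L) * dy)
  for (i in sample(length(x), 4))
    expect_equal(fd_grad(function(v) loss(v, W, b), x, i), g$dx[i],
                 tolerance = 1e-5)
  for (i in sample(length(W), 4))
    expect_equal(fd_grad(function(v) loss(x, v, b), W, i), g$dW[i],
                 tolerance = 1e-5)
  expect_equal(fd_grad(function(v) loss(x, W, v), b, 1), g$db[1],
               tolerance = 1e-5)
})

test_that("attention resblock gradients agree with finite differences", {
  set.seed(1)
  x <- array(rnorm(3 * 8 * 8 * 2), c(3, 8, 8, 2))
  penv <- new.env(parent = emptyenv())
  ctx <- ns$new_ctx(params = penv, training = TRUE, init = TRUE)
  set.seed(3)
  xid <- ns$op_input(ctx, x)
  out <- ns$ly_resblock(ctx, xid, "op", 4L, 2L)
  y <- ns$node_val(ctx, out)
  set.seed(9)
  dy <- array(rnorm(length(y)), dim(y))
  g <- ns$tape_backward(ctx, out, dy)
  loss <- function() {
    c2 <- ns$new_ctx(params = penv, training = TRUE, init = FALSE)
    i2 <- ns$op_input(c2, x)
    sum(ns$node_val(c2, ns$ly_resblock(c2, i2, "op", 4L, 2L)) * dy)
  }
  for (nm in ls(penv)) {
    p0 <- get(nm, envir = penv)
    i <- ((seq_len(min(2, length(p0))) * 7) %% length(p0)) + 1
    for (j in unique(i)) {
      h <- 1e-6
      assign(nm, `[<-`(p0, j, p0[j] + h), envir = penv); l1 <- loss()
      assign(nm, `[<-`(p0, j, p0[j] - h), envir = penv); l2 <- loss()
      assign(nm, p0, envir = penv)
      expect_equal((l1 - l2) / (2 * h), get(nm, envir = g)[j],
                   tolerance = 1e-4, label = nm)
    }
  }
})

test_that("whole-network dice-loss gradients agree with finite differences", {
  cfg <- model_config(num_levels = 2, base_channels = 4, dropout_rate = 0)
  net <- build_model(cfg, seed = 7)
  set.seed(42)
  imgs <- list(matrix(runif(256), 16, 16), matrix(runif(256), 16, 16))
  msk <- matrix(0, 16, 16); msk[5:9, 6:11] <- 1
  msks <- list(msk, t(msk))
  fb <- ns$msfa_forward_backward(net, imgs, msks)
  expect_true(is.finite(fb$loss))
  loss <- function() ns$msfa_forward_backward(net, imgs, msks)$loss
  set.seed(8)
  for (nm in sample(ls(net$params), 10)) {
    p0 <- get(nm, envir = net$params)
    j <- sample(length(p0), 1)
    h <- 1e-6
    assign(nm, `[<-`(p0, j, p0[j] + h), envir = net$params); l1 <- loss()
    assign(nm, `[<-`(p0, j, p0[j] - h), envir = net$params); l2 <- loss()
    assign(nm, p0, envir = net$params)
    expect_equal((l1 - l2) / (2 * h), get(nm, envir = fb$grads)[j],
                 tolerance = 1e-4, label = nm)
  }
})

test_that("batch norm switches between batch and running statistics", {
  set.seed(5)
  x <- array(rnorm(3 * 4 * 4 * 2, mean = 5, sd = 3), c(3, 4, 4, 2))
  penv <- new.env(parent = emptyenv())
  st <- new.env(parent = emptyenv())
  ctx <- ns$new_ctx(params = penv, bn_state = st, training = TRUE, init = TRUE)
  id <- ns$op_bn(ctx, ns$op_input(ctx, x), "bn")
  y <- ns$node_val(ctx, id)
  ym <- matrix(y, nrow = 3)
  expect_equal(rowMeans(ym), rep(0, 3), tolerance = 1e-12)  # standardized
  expect_equal(apply(ym, 1, stats::sd), rep(1, 3), tolerance = 0.05)
  # inference with identity statistics is the identity for gamma=1, beta=0
  st2 <- new.env(parent = emptyenv())
  ctx2 <- ns$new_ctx(params = penv, bn_state = st2, training = FALSE)
  id2 <- ns$op_bn(ctx2, ns$op_input(ctx2, x), "bn")
  expect_equal(ns$node_val(ctx2, id2), x, tolerance = 1e-4)
})
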