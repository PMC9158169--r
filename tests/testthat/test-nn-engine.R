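# Correctness of the network engine itself: forward oracles and
# finite-difference gradient checks.

naive_conv1d <- function(W, b, x) {
  # W: out x in x k; x: in x L x n; "same" padding, stride 1
  k <- dim(W)[3]
  L <- dim(x)[2]
  n <- dim(x)[3]
  pl <- (k - 1) %/% 2
  out <- array(0, c(dim(W)[1], L, n))
  for (s in seq_len(n)) for (j in seq_len(L)) {
    acc <- b
    for (t in seq_len(k)) {
      src <- j + t - 1 - pl
      if (src >= 1 && src <= L) acc <- acc + W[, , t] %*% x[, src, s]
    }
    out[, j, s] <- acc
  }
  out
}

test_that("conv1d forward matches a naive position-by-position oracle", {
  ns <- asNamespace("hmpi")
  set.seed(1)
  for (k in c(3, 4, 5)) {
    layer <- ns$nn_conv1d(3L, 5L, k)
    x <- array(rnorm(3 * 9 * 4), c(3, 9, 4))
    got <- ns$layer_forward(layer, x, training = FALSE)$out
    expect_equal(got, naive_conv1d(layer$W, layer$b, x), tolerance = 1e-12)
  }
})

numeric_grad <- function(f, p, eps = 1e-5) {
  g <- array(0, dim = dim(p) %||% length(p))
  for (i in seq_along(p)) {
    ph <- p; ph[i] <- ph[i] + eps
    pl <- p; pl[i] <- pl[i] - eps
    g[i] <- (f(ph) - f(pl)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("backprop gradients match finite differences for dense, conv and batchnorm", {
  ns <- asNamespace("hmpi")
  set.seed(2)
  x <- array(rnorm(2 * 7 * 3), c(2, 7, 3))
  layers <- list(ns$nn_conv1d(2L, 4L, 3L), ns$nn_leaky_relu(0.2),
                 ns$nn_flatten(), ns$nn_dense(28L, 6L), ns$nn_batchnorm(6L),
                 ns$nn_relu(), ns$nn_dense(6L, 2L))
  w_out <- matrix(rnorm(2 * 3), 2, 3)
  loss_of <- function(ls) sum(w_out * ns$seq_forward(ls, x, TRUE)$out)

  fw <- ns$seq_forward(layers, x, training = TRUE)
  bw <- ns$seq_backward(layers, fw$caches, w_out)
  for (i in seq_along(layers)) {
    for (pn in ns$nn_param_names(layers[[i]])) {
      fnum <- numeric_grad(function(p) {
        l2 <- layers; l2[[i]][[pn]] <- p; loss_of(l2)
      }, layers[[i]][[pn]])
      expect_equal(as.vector(bw$grads[[i]][[pn]]), as.vector(fnum),
                   tolerance = 1e-6,
                   label = paste("grad", i, layers[[i]]$type, pn))
    }
  }
  # input gradient
  gnum <- numeric_grad(function(xx) sum(w_out * ns$seq_forward(layers, xx, TRUE)$out), x)
  expect_equal(as.vector(bw$dx), as.vector(gnum), tolerance = 1e-6)
})

test_that("batch norm normalizes in training mode and freezes statistics in eval mode", {
  ns <- asNamespace("hmpi")
  set.seed(3)
  layer <- ns$nn_batchnorm(4L)
  x <- matrix(rnorm(4 * 50, mean = 3, sd = 2), 4, 50)
  r <- ns$layer_forward(layer, x, training = TRUE)
  expect_lt(max(abs(rowMeans(r$out))), 1e-8)
  expect_equal(apply(r$out, 1, function(v) sqrt(mean(v^2))), rep(1, 4),
               tolerance = 1e-2)
  # eval uses running stats: repeated eval calls are identical pure functions
  e1 <- ns$layer_forward(r$layer, x, training = FALSE)
  e2 <- ns$layer_forward(r$layer, x, training = FALSE)
  expect_identical(e1$out, e2$out)
})

test_that("dropout is inactive at evaluation and rescales at training", {
  ns <- asNamespace("hmpi")
  layer <- ns$nn_dropout(0.25)
  x <- matrix(1, 10, 200)
  ev <- ns$layer_forward(layer, x, training = FALSE)
  expect_identical(ev$out, x)
  set.seed(4)
  tr <- ns$layer_forward(layer, x, training = TRUE)
  expect_equal(mean(tr$out), 1, tolerance = 0.05)  # inverted scaling keeps E[x]
  expect_setequal(unique(as.vector(tr$out)), c(0, 1 / 0.75))
})

test_that("softmax losses and gradients agree with the scalar implementations", {
  ns <- asNamespace("hmpi")
  set.seed(5)
  logits <- matrix(rnorm(3 * 8), 3, 8)
  y <- sample(3, 8, replace = TRUE)
  for (eps in c(0, 0.2)) {
    r <- ns$xent_loss_grad(logits, y, eps)
    manual <- mean(vapply(1:8, function(i) {
      lsr_loss(softmax_probs(logits[, i]), y[i], eps)
    }, numeric(1)))
    expect_equal(r$loss, manual, tolerance = 1e-12)
    gnum <- numeric_grad(function(lg) ns$xent_loss_grad(lg, y, eps)$loss, logits)
    expect_equal(as.vector(r$dlogits), as.vector(gnum), tolerance = 1e-6)
  }
})

test_that("centre loss term and feature gradient match the exported joint loss", {
  ns <- asNamespace("hmpi")
  set.seed(6)
  f <- matrix(rnorm(4 * 6), 4, 6)
  y <- sample(2, 6, replace = TRUE)
  C <- matrix(rnorm(8), 4, 2)
  r <- ns$centre_loss_grad(f, y, C, lambda = 0.01)
  manual <- mean(vapply(1:6, function(i) {
    0.01 * sum((f[, i] - C[, y[i]])^2)
  }, numeric(1)))
  expect_equal(r$loss, manual, tolerance = 1e-12)
  gnum <- numeric_grad(function(ff) ns$centre_loss_grad(ff, y, C, 0.01)$loss, f)
  expect_equal(as.vector(r$df), as.vector(gnum), tolerance = 1e-6)
})
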