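# Minimal neural-network engine: layers, forward/backward, Adam.
#
# Everything is plain R built on BLAS matrix products. Conventions:
#   * dense activations are d x n matrices (features x batch),
#   * convolutional activations are ch x L x n arrays,
#   * a "layer" is a list with $type, parameter fields, and config,
#   * forward returns list(out, cache, layer) -- `layer` carries updated
#     running statistics (batch norm); backward returns list(dx, grads)
#     with grads named like the parameter fields.
# All randomness (init, dropout, shuffling) draws from the session RNG;
# trainers wrap themselves in with_seed() for reproducibility.

nn_dense <- function(in_dim, out_dim) {
  list(type = "dense",
       W = matrix(rnorm(out_dim * in_dim, sd = sqrt(2 / in_dim)), out_dim, in_dim),
       b = numeric(out_dim),
       in_dim = in_dim, out_dim = out_dim)
}

nn_conv1d <- function(in_ch, out_ch, kernel) {
  list(type = "conv1d",
       W = array(rnorm(out_ch * in_ch * kernel, sd = sqrt(2 / (in_ch * kernel))),
                 dim = c(out_ch, in_ch, kernel)),
       b = numeric(out_ch),
       in_ch = in_ch, out_ch = out_ch, kernel = kernel)
}

nn_leaky_relu <- function(alpha = 0.2) list(type = "leaky_relu", alpha = alpha)
nn_relu <- function() list(type = "relu")
nn_dropout <- function(rate) list(type = "dropout", rate = rate)
nn_flatten <- function() list(type = "flatten")

nn_batchnorm <- function(dim, momentum = 0.9, eps = 1e-3) {
  list(type = "batchnorm",
       gamma = rep(1, dim), beta = numeric(dim),
       run_mean = numeric(dim), run_var = rep(1, dim),
       momentum = momentum, eps = eps, dim = dim)
}

nn_param_names <- function(layer) {
  switch(layer$type,
         dense = c("W", "b"),
         conv1d = c("W", "b"),
         batchnorm = c("gamma", "beta"),
         character(0))
}

layer_forward <- function(layer, x, training) {
  switch(
    layer$type,
    dense = list(out = layer$W %*% x + layer$b, cache = x, layer = layer),
    conv1d = conv1d_forward(layer, x, training),
    leaky_relu = {
      neg <- x < 0
      out <- x
      out[neg] <- layer$alpha * x[neg]
      list(out = out, cache = neg, layer = layer)
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = mask, layer = layer)
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (runif(length(x)) >= layer$rate) / (1 - layer$rate)
        dim(mask) <- dim(x)
        list(out = x * mask, cache = mask, layer = layer)
      } else {
        list(out = x, cache = NULL, layer = layer)
      }
    },
    flatten = {
      d <- dim(x)
      out <- x
      dim(out) <- c(prod(d[-length(d)]), d[length(d)])
      list(out = out, cache = d, layer = layer)
    },
    batchnorm = batchnorm_forward(layer, x, training),
    abort(paste0("unknown layer type: ", layer$type))
  )
}

layer_backward <- function(layer, cache, dout) {
  switch(
    layer$type,
    dense = list(
      dx = crossprod(layer$W, dout),
      grads = list(W = tcrossprod(dout, cache), b = rowSums(dout))
    ),
    conv1d = conv1d_backward(layer, cache, dout),
    leaky_relu = {
      dx <- dout
      dx[cache] <- layer$alpha * dout[cache]
      list(dx = dx, grads = NULL)
    },
    relu = list(dx = dout * cache, grads = NULL),
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache, grads = NULL)
    },
    flatten = {
      dx <- dout
      dim(dx) <- cache
      list(dx = dx, grads = NULL)
    },
    batchnorm = batchnorm_backward(layer, cache, dout),
    abort(paste0("unknown layer type: ", layer$type))
  )
}

# 1-D convolution with "same" padding, stride 1: y = sum_t W[,,t] X_t + b,
# where X_t is the input shifted by kernel offset t.
conv1d_forward <- function(layer, x, training) {
  d <- dim(x)
  in_ch <- d[1L]; L <- d[2L]; n <- d[3L]
  k <- layer$kernel
  pl <- (k - 1L) %/% 2L
  xp <- array(0, dim = c(in_ch, L + k - 1L, n))
  xp[, pl + seq_len(L), ] <- x
  y <- matrix(0, layer$out_ch, L * n)
  for (t in seq_len(k)) {
    xt <- xp[, t:(t + L - 1L), , drop = FALSE]
    dim(xt) <- c(in_ch, L * n)
    y <- y + layer$W[, , t] %*% xt
  }
  y <- y + layer$b
  dim(y) <- c(layer$out_ch, L, n)
  list(out = y, cache = list(xp = xp, L = L, n = n), layer = layer)
}

conv1d_backward <- function(layer, cache, dout) {
  k <- layer$kernel
  in_ch <- layer$in_ch
  L <- cache$L; n <- cache$n
  pl <- (k - 1L) %/% 2L
  dy <- dout
  dim(dy) <- c(layer$out_ch, L * n)
  dW <- array(0, dim = dim(layer$W))
  dxp <- array(0, dim = dim(cache$xp))
  for (t in seq_len(k)) {
    xt <- cache$xp[, t:(t + L - 1L), , drop = FALSE]
    dim(xt) <- c(in_ch, L * n)
    dW[, , t] <- tcrossprod(dy, xt)
    dxt <- crossprod(layer$W[, , t], dy)
    dim(dxt) <- c(in_ch, L, n)
    dxp[, t:(t + L - 1L), ] <- dxp[, t:(t + L - 1L), ] + dxt
  }
  dx <- dxp[, pl + seq_len(L), , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = rowSums(dy)))
}

batchnorm_forward <- function(layer, x, training) {
  if (training) {
    n <- ncol(x)
    mu <- rowMeans(x)
    v <- rowMeans((x - mu)^2)
    inv_sd <- 1 / sqrt(v + layer$eps)
    xhat <- (x - mu) * inv_sd
    m <- layer$momentum
    layer$run_mean <- m * layer$run_mean + (1 - m) * mu
    layer$run_var <- m * layer$run_var + (1 - m) * v
    list(out = layer$gamma * xhat + layer$beta,
         cache = list(xhat = xhat, inv_sd = inv_sd, n = n),
         layer = layer)
  } else {
    inv_sd <- 1 / sqrt(layer$run_var + layer$eps)
    xhat <- (x - layer$run_mean) * inv_sd
    list(out = layer$gamma * xhat + layer$beta,
         cache = NULL, layer = layer)
  }
}

batchnorm_backward <- function(layer, cache, dout) {
  xhat <- cache$xhat
  n <- cache$n
  dgamma <- rowSums(dout * xhat)
  dbeta <- rowSums(dout)
  dxhat <- dout * layer$gamma
  dx <- (cache$inv_sd / n) *
    (n * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

seq_forward <- function(layers, x, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    if (!is.null(r$grads)) grads[[i]] <- r$grads  # NULL would delete the slot
  }
  list(dx = dout, grads = grads)
}

seq_n_params <- function(layers) {
  sum(vapply(layers, function(l) {
    sum(vapply(nn_param_names(l), function(p) length(l[[p]]), numeric(1)))
  }, numeric(1)))
}

# ---- Adam ------------------------------------------------------------------

adam_init_seq <- function(layers) {
  lapply(layers, function(l) {
    lapply(setNames(nm = nn_param_names(l)), function(p) {
      list(m = l[[p]] * 0, v = l[[p]] * 0)
    })
  })
}

adam_step_array <- function(p, g, st, t, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g * g
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

adam_step_seq <- function(layers, grads, state, t, lr) {
  for (i in seq_along(layers)) {
    for (pn in nn_param_names(layers[[i]])) {
      r <- adam_step_array(layers[[i]][[pn]], grads[[i]][[pn]],
                           state[[i]][[pn]], t, lr)
      layers[[i]][[pn]] <- r$p
      state[[i]][[pn]] <- r$st
    }
  }
  list(layers = layers, state = state)
}

# ---- batched softmax losses ------------------------------------------------

softmax_batch <- function(logits) {
  K <- nrow(logits)
  mx <- apply(logits, 2L, max)
  e <- exp(logits - rep(mx, each = K))
  e / rep(colSums(e), each = K)
}

# Target distribution matrix: one-hot columns, optionally label-smoothed.
target_matrix <- function(y, K, epsilon = 0) {
  n <- length(y)
  q <- matrix(epsilon / K, K, n)
  q[cbind(y, seq_len(n))] <- 1 - epsilon + epsilon / K
  q
}

# Mean cross-entropy of a batch against (possibly smoothed) targets,
# with gradient w.r.t. the logits.
xent_loss_grad <- function(logits, y, epsilon = 0) {
  n <- ncol(logits)
  K <- nrow(logits)
  p <- softmax_batch(logits)
  q <- target_matrix(y, K, epsilon)
  loss <- -sum(q * log(pmax(p, PROB_FLOOR))) / n
  list(loss = loss, dlogits = (p - q) / n, p = p)
}

# Centre-loss term lambda * mean_i ||f_i - c_{y_i}||^2 for a batch of
# features f (d x n) and centres C (d x K); returns the loss plus the
# gradients w.r.t. features and centres.
centre_loss_grad <- function(f, y, C, lambda) {
  n <- ncol(f)
  diff <- f - C[, y, drop = FALSE]
  loss <- lambda * sum(diff * diff) / n
  df <- (2 * lambda / n) * diff
  dC <- matrix(0, nrow(C), ncol(C))
  for (k in unique(y)) {
    dC[, k] <- -rowSums(df[, y == k, drop = FALSE])
  }
  list(loss = loss, df = df, dC = dC)
}

# Minibatch index blocks for one epoch; a trailing singleton batch is
# merged into its predecessor so batch statistics stay defined.
minibatches <- function(n, batch_size, shuffle = TRUE) {
  idx <- if (shuffle) sample.int(n) else seq_len(n)
  starts <- seq(1L, n, by = batch_size)
  blocks <- lapply(starts, function(s) idx[s:min(s + batch_size - 1L, n)])
  nb <- length(blocks)
  if (nb > 1L && length(blocks[[nb]]) == 1L) {
    blocks[[nb - 1L]] <- c(blocks[[nb - 1L]], blocks[[nb]])
    blocks[[nb]] <- NULL
  }
  blocks
}

slice_batch <- function(x, idx) {
  if (length(dim(x)) == 3L) x[, , idx, drop = FALSE] else x[, idx, drop = FALSE]
}

# Moving-average class-centre update (Wen et al. rule): each centre moves
# a fraction alpha towards the mean of its class members in the batch.
update_centres <- function(C, f, y, alpha = 0.5) {
  for (k in unique(y)) {
    members <- f[, y == k, drop = FALSE]
    delta <- rowSums(C[, k] - members) / (1 + ncol(members))
    C[, k] <- C[, k] - alpha * delta
  }
  C
}
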