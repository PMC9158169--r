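#' PSFN: the convolutional sequence branch
#'
#' The promoter sequence features network (PSFN) reads the one-hot
#' `4 x L` encoding through three convolutional blocks, each
#' `Dropout(LeakyReLU(conv(x)))`: 32 feature maps of kernel size 3
#' (fine-grained local signal), 64 maps of kernel 4 (medium-grained) and
#' 128 maps of kernel 5 (coarse local features); `alpha = 0.2` in the
#' LeakyReLU and dropout probability 0.25. The last block's output is
#' flattened and a fully connected ReLU layer produces the sequence
#' feature vector; a `K`-way softmax head classifies it. Training
#' minimizes the joint objective `-log p(y) + lambda * ||x - c_y||^2`
#' (cross-entropy plus centre loss), with the class centres `c_y` held
#' in an embedding updated jointly by the optimizer; `lambda = 0`
#' recovers plain cross-entropy training (the "PSFNcce" configuration).
#'
#' Convolutions use "same" padding and stride 1 (no pooling), so
#' positional resolution is preserved up to the flatten.
#'
#' @param input_length Sequence length `L` the model accepts (251 for
#'   the eukaryotic window convention, 81 for the prokaryotic one).
#' @param num_classes Number of classes `K` (2 for identification).
#' @param block_filters Feature-map counts of the three blocks.
#' @param block_kernels Kernel sizes of the three blocks.
#' @param leaky_alpha Negative slope of the LeakyReLU.
#' @param dropout_rate Dropout probability inside each block.
#' @param feature_dim Width of the fully connected feature layer.
#' @param lambda_centre Centre-loss weight `lambda` (0.01 by default;
#'   0 disables the centre loss).
#' @param centre_alpha Learning rate of the class-centre moving-average
#'   update (default 0.5). Centres are refreshed each minibatch by
#'   `c_k <- c_k + alpha * mean(x_i - c_k)` over the batch members of
#'   class `k`, so they track the class means at feature scale while the
#'   centre-loss gradient acts on the features themselves.
#' @param learning_rate,batch_size,epochs,patience Adam optimizer
#'   settings; `patience` is the early-stopping patience on validation
#'   loss (ignored without a validation set).
#' @param seed Integer seed governing initialization, shuffling and
#'   dropout.
#' @return `psfn_spec`: a spec list. `build_psfn`: an untrained
#'   `psfn_model`.
#' @examples
#' spec <- psfn_spec(input_length = 81, feature_dim = 16, epochs = 2)
#' model <- build_psfn(spec)
#' model
#' @export
psfn_spec <- function(input_length,
                      num_classes = 2L,
                      block_filters = c(32L, 64L, 128L),
                      block_kernels = c(3L, 4L, 5L),
                      leaky_alpha = 0.2,
                      dropout_rate = 0.25,
                      feature_dim = 128L,
                      lambda_centre = 0.01,
                      centre_alpha = 0.5,
                      learning_rate = 1e-3,
                      batch_size = 64L,
                      epochs = 50L,
                      patience = 5L,
                      seed = 1L) {
  stopifnot(length(block_filters) == 3L, length(block_kernels) == 3L,
            dropout_rate >= 0, dropout_rate < 1, lambda_centre >= 0,
            num_classes >= 2L)
  structure(
    list(input_length = as.integer(input_length),
         num_classes = as.integer(num_classes),
         block_filters = as.integer(block_filters),
         block_kernels = as.integer(block_kernels),
         leaky_alpha = leaky_alpha, dropout_rate = dropout_rate,
         feature_dim = as.integer(feature_dim),
         lambda_centre = lambda_centre, centre_alpha = centre_alpha,
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "psfn_spec"
  )
}

#' @rdname psfn_spec
#' @param spec A `psfn_spec`.
#' @export
build_psfn <- function(spec) {
  stopifnot(inherits(spec, "psfn_spec"))
  L <- spec$input_length
  min_L <- max(spec$block_kernels)
  if (L < min_L) {
    abort(paste0("input_length ", L, " is shorter than the largest kernel; ",
                 "minimal supported length is ", min_L))
  }
  with_seed(spec$seed, {
    f <- spec$block_filters
    k <- spec$block_kernels
    stack <- list(
      nn_conv1d(4L, f[1L], k[1L]), nn_leaky_relu(spec$leaky_alpha),
      nn_dropout(spec$dropout_rate),
      nn_conv1d(f[1L], f[2L], k[2L]), nn_leaky_relu(spec$leaky_alpha),
      nn_dropout(spec$dropout_rate),
      nn_conv1d(f[2L], f[3L], k[3L]), nn_leaky_relu(spec$leaky_alpha),
      nn_dropout(spec$dropout_rate),
      nn_flatten(),
      nn_dense(f[3L] * L, spec$feature_dim), nn_relu()
    )
    head <- nn_dense(spec$feature_dim, spec$num_classes)
    centres <- matrix(rnorm(spec$feature_dim * spec$num_classes, sd = 0.05),
                      spec$feature_dim, spec$num_classes)
    structure(
      list(spec = spec, stack = stack, head = head, centres = centres,
           classes = NULL, trained = FALSE, log = NULL),
      class = "psfn_model"
    )
  })
}

#' Train the PSFN
#'
#' Runs Adam on the joint cross-entropy + centre loss over minibatches of
#' one-hot encoded sequences. With a validation set, training stops early
#' when validation loss has not improved for `patience` epochs and the
#' best parameters are restored. Fully reproducible given the spec seed.
#'
#' @param model A `psfn_model` from [build_psfn()].
#' @param train An [encode_records()] dataset with one-hot encodings and
#'   labels.
#' @param valid Optional validation dataset of the same shape.
#' @return The trained model; the per-epoch log (`epoch`, `loss`,
#'   `val_loss`, `val_acc`) is in `model$log`.
#' @examples
#' \donttest{
#' recs <- simulate_promoters(n_per_class = 60, length = 30, seed = 2)
#' enc <- encode_records(recs)
#' m <- build_psfn(psfn_spec(30, feature_dim = 16, epochs = 3, seed = 2))
#' m <- train_psfn(m, enc)
#' tail(m$log)
#' }
#' @export
train_psfn <- function(model, train, valid = NULL) {
  stopifnot(inherits(model, "psfn_model"))
  check_encoded(train, "onehot", model$spec$input_length, model$spec$num_classes)
  spec <- model$spec
  model$classes <- train$classes
  x_all <- train$onehot
  y_all <- train$labels
  with_seed(spec$seed + 1L, {
    st_stack <- adam_init_seq(model$stack)
    st_head <- adam_init_seq(list(model$head))
    t_step <- 0L
    log <- list()
    best <- list(val_loss = Inf, stale = 0L, model = NULL)
    n <- dim(x_all)[3L]
    for (epoch in seq_len(spec$epochs)) {
      batch_losses <- c()
      for (idx in minibatches(n, spec$batch_size)) {
        xb <- x_all[, , idx, drop = FALSE]
        yb <- y_all[idx]
        fw <- seq_forward(model$stack, xb, training = TRUE)
        model$stack <- fw$layers
        feats <- fw$out
        logits <- model$head$W %*% feats + model$head$b
        xe <- xent_loss_grad(logits, yb)
        cl <- centre_loss_grad(feats, yb, model$centres, spec$lambda_centre)
        batch_losses <- c(batch_losses, xe$loss + cl$loss)
        if (!is.finite(xe$loss + cl$loss)) {
          abort(paste0("training diverged (non-finite loss) at epoch ", epoch))
        }
        hb <- layer_backward(model$head, feats, xe$dlogits)
        dfeats <- hb$dx + cl$df
        bw <- seq_backward(model$stack, fw$caches, dfeats)
        t_step <- t_step + 1L
        up <- adam_step_seq(model$stack, bw$grads, st_stack, t_step,
                            spec$learning_rate)
        model$stack <- up$layers; st_stack <- up$state
        up <- adam_step_seq(list(model$head), list(hb$grads), st_head, t_step,
                            spec$learning_rate)
        model$head <- up$layers[[1L]]; st_head <- up$state
        if (spec$lambda_centre > 0) {
          model$centres <- update_centres(model$centres, feats, yb,
                                          spec$centre_alpha)
        }
      }
      row <- tibble(epoch = epoch, loss = mean(batch_losses),
                    val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(valid)) {
        ev <- psfn_eval(model, valid)
        row$val_loss <- ev$loss
        row$val_acc <- ev$acc
        if (ev$loss < best$val_loss - 1e-6) {
          best$val_loss <- ev$loss
          best$stale <- 0L
          best$model <- model[c("stack", "head", "centres")]
        } else {
          best$stale <- best$stale + 1L
        }
      }
      log[[epoch]] <- row
      if (!is.null(valid) && best$stale >= spec$patience) break
    }
    if (!is.null(best$model)) {
      model[c("stack", "head", "centres")] <- best$model
    }
    model$trained <- TRUE
    model$log <- new_training_log(dplyr::bind_rows(log), "psfn")
    model
  })
}

psfn_eval <- function(model, data) {
  p <- psfn_forward_probs(model, data$onehot)
  y <- data$labels
  n <- length(y)
  loss <- -mean(log(pmax(p[cbind(y, seq_len(n))], PROB_FLOOR)))
  acc <- mean(max.col(t(p)) == y)
  list(loss = loss, acc = acc, p = p)
}

psfn_forward_probs <- function(model, x) {
  fw <- seq_forward(model$stack, x, training = FALSE)
  softmax_batch(model$head$W %*% fw$out + model$head$b)
}

#' Predicted class probabilities from the PSFN
#'
#' @param object A trained `psfn_model`.
#' @param data An encoded dataset with one-hot encodings.
#' @param ... Unused.
#' @return An `n x K` matrix of class probabilities (columns named by
#'   class when known).
#' @export
predict.psfn_model <- function(object, data, ...) {
  check_encoded(data, "onehot", object$spec$input_length)
  p <- t(psfn_forward_probs(object, data$onehot))
  colnames(p) <- object$classes
  p
}

#' Extract learned sequence features
#'
#' `"feature_layer"` returns the activations of the fully connected
#' feature layer (the representation supervised by the centre loss).
#' `"second_block"` returns the second convolution block's output with
#' global average pooling over positions — the fixed-length transferred
#' representation used for ADASYN resampling in the subtype variant,
#' where the raw one-hot space is unsuitable for interpolation.
#'
#' @param model A trained `psfn_model`.
#' @param data An encoded dataset with one-hot encodings.
#' @param layer `"feature_layer"` or `"second_block"`.
#' @return An `n x d` feature matrix (`d = feature_dim` or the second
#'   block's filter count).
#' @export
extract_features <- function(model, data, layer = c("feature_layer", "second_block")) {
  stopifnot(inherits(model, "psfn_model"))
  layer <- match.arg(layer)
  check_encoded(data, "onehot", model$spec$input_length)
  if (layer == "feature_layer") {
    fw <- seq_forward(model$stack, data$onehot, training = FALSE)
    return(t(fw$out))
  }
  # layers 1..6 are conv block 1 and conv block 2
  out <- psfn_block2_maps(model, data)            # filters x L x n
  pooled <- colMeans(aperm(out, c(2L, 1L, 3L)))   # mean over positions
  t(pooled)
}

# Full block-2 feature maps (filters x L x n), evaluation mode.
psfn_block2_maps <- function(model, data) {
  seq_forward(model$stack[1:6], data$onehot, training = FALSE)$out
}

# Run the transferred upper PSFN layers (block 3 onward) on block-2
# feature maps, returning the feature-layer activations (dim x n).
psfn_features_from_block2 <- function(model, maps) {
  seq_forward(model$stack[7:length(model$stack)], maps, training = FALSE)$out
}

#' @export
print.psfn_model <- function(x, ...) {
  s <- x$spec
  cat("<psfn_model> ", if (x$trained) "trained" else "untrained",
      "; L = ", s$input_length, ", K = ", s$num_classes, "\n", sep = "")
  cat("  conv blocks: ",
      paste(sprintf("%d maps (kernel %d)", s$block_filters, s$block_kernels),
            collapse = " -> "), "\n", sep = "")
  cat("  feature dim ", s$feature_dim, ", lambda_centre ", s$lambda_centre,
      ", dropout ", s$dropout_rate, ", LeakyReLU alpha ", s$leaky_alpha,
      "\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy psfn_model
tidy.psfn_model <- function(x, ...) {
  if (is.null(x$log)) abort("model has no training log; train it first")
  x$log
}

#' @export
#' @method glance psfn_model
glance.psfn_model <- function(x, ...) {
  tibble(
    trained = x$trained,
    epochs_run = if (is.null(x$log)) 0L else nrow(x$log),
    final_loss = if (is.null(x$log)) NA_real_ else x$log$loss[nrow(x$log)],
    final_val_acc = if (is.null(x$log)) NA_real_ else x$log$val_acc[nrow(x$log)],
    n_parameters = seq_n_params(x$stack) + seq_n_params(list(x$head)) +
      length(x$centres),
    lambda_centre = x$spec$lambda_centre
  )
}

check_encoded <- function(data, need = c("onehot", "sp"), input_length = NULL,
                          num_classes = NULL) {
  if (!inherits(data, "encoded_dataset")) {
    abort("data must be an encoded_dataset from encode_records()")
  }
  for (w in need) {
    if (is.null(data[[w]])) abort(paste0("dataset lacks the '", w, "' encoding"))
  }
  if (!is.null(input_length) && data$length != input_length) {
    abort(paste0("model expects sequences of length ", input_length,
                 ", dataset has length ", data$length))
  }
  if (!is.null(num_classes) && !is.null(data$labels) &&
      length(unique(data$labels)) > num_classes) {
    abort("dataset has more classes than the model's num_classes")
  }
  invisible(data)
}

new_training_log <- function(df, branch) {
  attr(df, "branch") <- branch
  class(df) <- c("training_log", class(df))
  df
}

#' @export
#' @method autoplot training_log
autoplot.training_log <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              dplyr::any_of(c("loss", "val_loss", "val_acc")),
                              names_to = "series", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = paste0("Training trace (", attr(object, "branch"), ")")) +
    ggplot2::theme_minimal()
}
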