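#' DSPN: the densely linked structural branch
#'
#' The deep structural profiles network (DSPN) models the flattened
#' `12 x (L - 1)` structural-profile matrix with seven fully connected
#' blocks, each composed as
#' `BatchNorm(Dropout(LeakyReLU(Dense(x))))` with dropout probability
#' 0.2. Skip links make the network densely connected: the flattened
#' structural-profile input is concatenated into the inputs of blocks 3
#' and 6, and the output of block 2 is additionally concatenated into
#' block 6. Block 7 (width 128) emits the structural feature vector; a
#' `K`-way softmax head trained with plain cross-entropy classifies it.
#'
#' Block widths default to `(250, 1000, 250, 1000, 1500, 1000, 128)` for
#' the 251 bp eukaryotic window and `(80, 500, 80, 150, 500, 500, 128)`
#' for the 81 bp prokaryotic window; pass `preset = "prokaryote"` or an
#' explicit `block_sizes` vector. The profile matrix is flattened
#' property-major (row-major) before the first dense layer.
#'
#' @param input_length Sequence length `L`; the network input width is
#'   `12 * (L - 1)`.
#' @param num_classes Number of classes `K`.
#' @param preset `"eukaryote"` or `"prokaryote"` block-width preset.
#' @param block_sizes Optional explicit 7 block widths (overrides
#'   `preset`); the 7th is the structural feature dimension.
#' @param leaky_alpha Negative slope of the LeakyReLU (shared convention
#'   with the sequence branch).
#' @param dropout_rate Dropout probability inside each block.
#' @inheritParams psfn_spec
#' @return `dspn_spec`: a spec list. `build_dspn`: an untrained
#'   `dspn_model`.
#' @examples
#' spec <- dspn_spec(81, preset = "prokaryote", epochs = 2)
#' spec$block_sizes
#' @export
dspn_spec <- function(input_length,
                      num_classes = 2L,
                      preset = c("eukaryote", "prokaryote"),
                      block_sizes = NULL,
                      leaky_alpha = 0.2,
                      dropout_rate = 0.2,
                      learning_rate = 1e-3,
                      batch_size = 64L,
                      epochs = 50L,
                      patience = 5L,
                      seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(block_sizes)) {
    block_sizes <- switch(preset,
                          eukaryote = c(250L, 1000L, 250L, 1000L, 1500L, 1000L, 128L),
                          prokaryote = c(80L, 500L, 80L, 150L, 500L, 500L, 128L))
  }
  if (length(block_sizes) != 7L) abort("block_sizes must have exactly 7 entries")
  stopifnot(input_length >= 2L, dropout_rate >= 0, dropout_rate < 1,
            num_classes >= 2L)
  structure(
    list(input_length = as.integer(input_length),
         input_dim = 12L * (as.integer(input_length) - 1L),
         num_classes = as.integer(num_classes),
         preset = preset,
         block_sizes = as.integer(block_sizes),
         skip_inputs_to = c(3L, 6L), skip_block2_to = 6L,
         leaky_alpha = leaky_alpha, dropout_rate = dropout_rate,
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "dspn_spec"
  )
}

# Input width of each of the seven blocks given the skip concatenations.
dspn_block_input_dims <- function(spec) {
  w <- spec$block_sizes
  D0 <- spec$input_dim
  c(D0,                  # block 1: the flattened SP matrix
    w[1L],               # block 2
    w[2L] + D0,          # block 3: block-2 output ++ SP input
    w[3L],               # block 4
    w[4L],               # block 5
    w[5L] + D0 + w[2L],  # block 6: block-5 ++ SP input ++ block-2
    w[6L])               # block 7
}

#' @rdname dspn_spec
#' @param spec A `dspn_spec`.
#' @export
build_dspn <- function(spec) {
  stopifnot(inherits(spec, "dspn_spec"))
  with_seed(spec$seed, {
    in_dims <- dspn_block_input_dims(spec)
    blocks <- lapply(seq_len(7L), function(i) {
      list(
        nn_dense(in_dims[i], spec$block_sizes[i]),
        nn_leaky_relu(spec$leaky_alpha),
        nn_dropout(spec$dropout_rate),
        nn_batchnorm(spec$block_sizes[i])
      )
    })
    head <- nn_dense(spec$block_sizes[7L], spec$num_classes)
    structure(
      list(spec = spec, blocks = blocks, head = head,
           classes = NULL, trained = FALSE, log = NULL),
      class = "dspn_model"
    )
  })
}

# Forward pass through the dense blocks with skip concatenations.
# Returns block outputs, caches and updated blocks (batch-norm stats).
dspn_forward <- function(model, x0, training) {
  blocks <- model$blocks
  outs <- vector("list", 7L)
  caches <- vector("list", 7L)
  run <- function(i, x) {
    r <- seq_forward(blocks[[i]], x, training)
    blocks[[i]] <<- r$layers
    caches[[i]] <<- r$caches
    outs[[i]] <<- r$out
    r$out
  }
  o1 <- run(1L, x0)
  o2 <- run(2L, o1)
  o3 <- run(3L, rbind(o2, x0))
  o4 <- run(4L, o3)
  o5 <- run(5L, o4)
  o6 <- run(6L, rbind(o5, x0, o2))
  o7 <- run(7L, o6)
  list(outs = outs, caches = caches, blocks = blocks, features = o7)
}

# Backward through the dense blocks; returns per-block grads and the
# gradient w.r.t. the input (accumulated over the direct path and the
# two skip paths).
dspn_backward <- function(model, fw, dfeatures) {
  spec <- model$spec
  w <- spec$block_sizes
  D0 <- spec$input_dim
  grads <- vector("list", 7L)
  back <- function(i, dout) {
    r <- seq_backward(fw$blocks[[i]], fw$caches[[i]], dout)
    grads[[i]] <<- r$grads
    r$dx
  }
  d6 <- back(7L, dfeatures)
  dcat6 <- back(6L, d6)
  do5 <- dcat6[seq_len(w[5L]), , drop = FALSE]
  dx0 <- dcat6[w[5L] + seq_len(D0), , drop = FALSE]
  do2 <- dcat6[w[5L] + D0 + seq_len(w[2L]), , drop = FALSE]
  do4 <- back(5L, do5)
  do3 <- back(4L, do4)
  dcat3 <- back(3L, do3)
  do2 <- do2 + dcat3[seq_len(w[2L]), , drop = FALSE]
  dx0 <- dx0 + dcat3[w[2L] + seq_len(D0), , drop = FALSE]
  do1 <- back(2L, do2)
  dx0 <- dx0 + back(1L, do1)
  list(grads = grads, dx0 = dx0)
}

#' Train the DSPN
#'
#' Runs Adam on the categorical cross-entropy over minibatches of
#' flattened structural-profile matrices. Batch-norm statistics are
#' updated in training mode and frozen at evaluation. Early stopping and
#' reproducibility behave as in [train_psfn()].
#'
#' @param model A `dspn_model` from [build_dspn()].
#' @param train An [encode_records()] dataset with structural encodings
#'   and labels.
#' @param valid Optional validation dataset.
#' @return The trained model with `model$log`.
#' @export
train_dspn <- function(model, train, valid = NULL) {
  stopifnot(inherits(model, "dspn_model"))
  check_encoded(train, "sp", model$spec$input_length, model$spec$num_classes)
  spec <- model$spec
  model$classes <- train$classes
  x_all <- flatten_sp(train$sp)
  y_all <- train$labels
  x_val <- if (!is.null(valid)) flatten_sp(valid$sp)
  with_seed(spec$seed + 1L, {
    st_blocks <- lapply(model$blocks, adam_init_seq)
    st_head <- adam_init_seq(list(model$head))
    t_step <- 0L
    log <- list()
    best <- list(val_loss = Inf, stale = 0L, model = NULL)
    n <- ncol(x_all)
    for (epoch in seq_len(spec$epochs)) {
      batch_losses <- c()
      for (idx in minibatches(n, spec$batch_size)) {
        xb <- x_all[, idx, drop = FALSE]
        yb <- y_all[idx]
        fw <- dspn_forward(model, xb, training = TRUE)
        model$blocks <- fw$blocks
        logits <- model$head$W %*% fw$features + model$head$b
        xe <- xent_loss_grad(logits, yb)
        batch_losses <- c(batch_losses, xe$loss)
        if (!is.finite(xe$loss)) {
          abort(paste0("training diverged (non-finite loss) at epoch ", epoch))
        }
        hb <- layer_backward(model$head, fw$features, xe$dlogits)
        bw <- dspn_backward(model, fw, hb$dx)
        t_step <- t_step + 1L
        for (i in seq_len(7L)) {
          up <- adam_step_seq(model$blocks[[i]], bw$grads[[i]], st_blocks[[i]],
                              t_step, spec$learning_rate)
          model$blocks[[i]] <- up$layers
          st_blocks[[i]] <- up$state
        }
        up <- adam_step_seq(list(model$head), list(hb$grads), st_head, t_step,
                            spec$learning_rate)
        model$head <- up$layers[[1L]]
        st_head <- up$state
      }
      row <- tibble(epoch = epoch, loss = mean(batch_losses),
                    val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(valid)) {
        p <- dspn_forward_probs(model, x_val)
        yv <- valid$labels
        row$val_loss <- -mean(log(pmax(p[cbind(yv, seq_along(yv))], PROB_FLOOR)))
        row$val_acc <- mean(max.col(t(p)) == yv)
        if (row$val_loss < best$val_loss - 1e-6) {
          best$val_loss <- row$val_loss
          best$stale <- 0L
          best$model <- model[c("blocks", "head")]
        } else {
          best$stale <- best$stale + 1L
        }
      }
      log[[epoch]] <- row
      if (!is.null(valid) && best$stale >= spec$patience) break
    }
    if (!is.null(best$model)) model[c("blocks", "head")] <- best$model
    model$trained <- TRUE
    model$log <- new_training_log(dplyr::bind_rows(log), "dspn")
    model
  })
}

dspn_forward_probs <- function(model, x) {
  fw <- dspn_forward(model, x, training = FALSE)
  softmax_batch(model$head$W %*% fw$features + model$head$b)
}

# Row-major (property-major) flattening of the 12 x (L-1) x n array.
flatten_sp <- function(sp) {
  d <- dim(sp)
  out <- sp
  dim(out) <- c(d[1L] * d[2L], d[3L])
  out
}

#' Predicted class probabilities from the DSPN
#'
#' @param object A trained `dspn_model`.
#' @param data An encoded dataset with structural encodings.
#' @param ... Unused.
#' @return An `n x K` probability matrix.
#' @export
predict.dspn_model <- function(object, data, ...) {
  check_encoded(data, "sp", object$spec$input_length)
  p <- t(dspn_forward_probs(object, flatten_sp(data$sp)))
  colnames(p) <- object$classes
  p
}

#' Extract learned structural features
#'
#' Returns the block-7 activations (the 128-dimensional structural
#' feature vector) for each sample, in evaluation mode.
#'
#' @param model A trained `dspn_model`.
#' @param data An encoded dataset with structural encodings.
#' @return An `n x 128` feature matrix (width = 7th block size).
#' @export
extract_structural_features <- function(model, data) {
  stopifnot(inherits(model, "dspn_model"))
  check_encoded(data, "sp", model$spec$input_length)
  fw <- dspn_forward(model, flatten_sp(data$sp), training = FALSE)
  t(fw$features)
}

#' @export
print.dspn_model <- function(x, ...) {
  s <- x$spec
  cat("<dspn_model> ", if (x$trained) "trained" else "untrained",
      "; input 12 x ", s$input_length - 1L, " (width ", s$input_dim,
      "), K = ", s$num_classes, "\n", sep = "")
  cat("  block widths: ", paste(s$block_sizes, collapse = ", "),
      " (", s$preset, " preset)\n", sep = "")
  cat("  skips: SP input -> blocks ", paste(s$skip_inputs_to, collapse = ", "),
      "; block 2 -> block ", s$skip_block2_to, "\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy dspn_model
tidy.dspn_model <- function(x, ...) {
  if (is.null(x$log)) abort("model has no training log; train it first")
  x$log
}

#' @export
#' @method glance dspn_model
glance.dspn_model <- function(x, ...) {
  tibble(
    trained = x$trained,
    epochs_run = if (is.null(x$log)) 0L else nrow(x$log),
    final_loss = if (is.null(x$log)) NA_real_ else x$log$loss[nrow(x$log)],
    final_val_acc = if (is.null(x$log)) NA_real_ else x$log$val_acc[nrow(x$log)],
    n_parameters = sum(vapply(x$blocks, seq_n_params, numeric(1))) +
      seq_n_params(list(x$head))
  )
}
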