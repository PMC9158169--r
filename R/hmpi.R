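#' HMPI: the hybrid sequence + structure classifier
#'
#' The hybrid model concatenates the PSFN sequence feature vector and the
#' DSPN structural feature vector into one representation and classifies
#' it with a fully connected layer followed by a `K`-way softmax head.
#' Variants:
#' \describe{
#'   \item{`base`}{cross-entropy head.}
#'   \item{`lsr`}{identical architecture; the head loss is the
#'     label-smoothing-regularized cross-entropy ([lsr_loss()]) with
#'     `epsilon = 0.2`. Nothing else changes.}
#'   \item{`at`}{trained via [run_hmpiat()]: ADASYN oversampling of
#'     minority classes in transferred feature space (PSFN second
#'     convolution block, globally average-pooled, concatenated with the
#'     DSPN structural features) before head training.}
#' }
#' Two training regimes are available: `"pretrain_then_head"` (default)
#' trains each branch on its own objective, freezes them, and trains the
#' fusion head on the concatenated features; `"joint"` trains everything
#' end-to-end, summing the head loss and the centre-loss term on the
#' sequence features.
#'
#' @param psfn A [psfn_spec()].
#' @param dspn A [dspn_spec()] with the same `input_length` and
#'   `num_classes`.
#' @param head_hidden Width of the fusion Dense layer (default 64).
#' @param variant `"base"`, `"at"` or `"lsr"`.
#' @param epsilon Label-smoothing weight for the `lsr` variant.
#' @param adasyn_k,adasyn_balance ADASYN neighbourhood size and balance
#'   level for the `at` variant.
#' @param regime `"pretrain_then_head"` or `"joint"`.
#' @param learning_rate,batch_size,epochs,patience,seed Fusion-head
#'   optimizer settings (branch training uses each branch spec's own).
#' @return `hmpi_spec`: a spec list. `build_hmpi`: an untrained
#'   `hmpi_model` containing both branch models and the fusion head.
#' @examples
#' spec <- hmpi_spec(psfn_spec(30, feature_dim = 16, epochs = 2),
#'                   dspn_spec(30, block_sizes = rep(16, 7), epochs = 2))
#' model <- build_hmpi(spec)
#' model
#' @export
hmpi_spec <- function(psfn,
                      dspn,
                      head_hidden = 64L,
                      variant = c("base", "at", "lsr"),
                      epsilon = 0.2,
                      adasyn_k = 5L,
                      adasyn_balance = 1.0,
                      regime = c("pretrain_then_head", "joint"),
                      learning_rate = 1e-3,
                      batch_size = 64L,
                      epochs = 50L,
                      patience = 5L,
                      seed = 1L) {
  stopifnot(inherits(psfn, "psfn_spec"), inherits(dspn, "dspn_spec"))
  if (psfn$input_length != dspn$input_length) {
    abort("branch specs disagree on input_length")
  }
  if (psfn$num_classes != dspn$num_classes) {
    abort("branch specs disagree on num_classes")
  }
  variant <- match.arg(variant)
  regime <- match.arg(regime)
  if (epsilon < 0 || epsilon >= 1) abort("epsilon must lie in [0, 1)")
  structure(
    list(psfn = psfn, dspn = dspn,
         head_hidden = as.integer(head_hidden),
         variant = variant, epsilon = epsilon,
         adasyn_k = as.integer(adasyn_k), adasyn_balance = adasyn_balance,
         regime = regime,
         fused_dim = psfn$feature_dim + dspn$block_sizes[7L],
         num_classes = psfn$num_classes,
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "hmpi_spec"
  )
}

#' @rdname hmpi_spec
#' @param spec An `hmpi_spec`.
#' @export
build_hmpi <- function(spec) {
  stopifnot(inherits(spec, "hmpi_spec"))
  psfn <- build_psfn(spec$psfn)
  dspn <- build_dspn(spec$dspn)
  head <- with_seed(spec$seed, {
    list(nn_dense(spec$fused_dim, spec$head_hidden),
         nn_relu(),
         nn_dense(spec$head_hidden, spec$num_classes))
  })
  structure(
    list(spec = spec, psfn = psfn, dspn = dspn, head = head,
         at_head = NULL, mode = spec$variant, classes = NULL,
         trained = FALSE, log = NULL),
    class = "hmpi_model"
  )
}

#' Train the hybrid model
#'
#' Under the default `"pretrain_then_head"` regime the PSFN is trained on
#' the joint cross-entropy + centre loss, the DSPN on cross-entropy, both
#' branches are frozen, and the fusion head is trained on the
#' concatenated features (cross-entropy, or its label-smoothed form for
#' `variant = "lsr"`). Under `"joint"` the whole network trains
#' end-to-end on the head loss plus the centre-loss term on the sequence
#' features. The regime that ran is recorded in the training log.
#'
#' @param model An `hmpi_model` from [build_hmpi()].
#' @param train An [encode_records()] dataset with both encodings and
#'   labels.
#' @param valid Optional validation dataset.
#' @param reuse_branches If `TRUE` and both branch models are already
#'   trained (e.g. inspected standalone first), the staged regime skips
#'   branch training and only fits the fusion head.
#' @return The trained model; `model$log` holds the fusion-stage log with
#'   attribute `"regime"`.
#' @export
train_hmpi <- function(model, train, valid = NULL, reuse_branches = FALSE) {
  stopifnot(inherits(model, "hmpi_model"))
  spec <- model$spec
  check_encoded(train, c("onehot", "sp"), spec$psfn$input_length,
                spec$num_classes)
  model$classes <- train$classes
  eps <- if (spec$variant == "lsr") spec$epsilon else 0
  if (spec$regime == "pretrain_then_head") {
    if (!(reuse_branches && model$psfn$trained && model$dspn$trained)) {
      model$psfn <- train_psfn(model$psfn, train, valid)
      model$dspn <- train_dspn(model$dspn, train, valid)
    }
    X <- t(cbind(extract_features(model$psfn, train, "feature_layer"),
                 extract_structural_features(model$dspn, train)))
    Xv <- NULL
    if (!is.null(valid)) {
      Xv <- t(cbind(extract_features(model$psfn, valid, "feature_layer"),
                    extract_structural_features(model$dspn, valid)))
    }
    fit <- train_feature_head(model$head, X, train$labels, epsilon = eps,
                              lr = spec$learning_rate,
                              batch_size = spec$batch_size,
                              epochs = spec$epochs, patience = spec$patience,
                              seed = spec$seed,
                              x_valid = Xv,
                              y_valid = if (!is.null(valid)) valid$labels)
    model$head <- fit$layers
    log <- fit$log
  } else {
    fit <- train_hmpi_joint(model, train, valid)
    model <- fit$model
    log <- fit$log
  }
  attr(log, "regime") <- spec$regime
  attr(log, "variant") <- spec$variant
  model$log <- new_training_log(log, paste0("hmpi/", spec$regime))
  model$mode <- spec$variant
  model$trained <- TRUE
  model
}

# End-to-end training: head loss (CCE or LSR) backpropagated through the
# fusion head into both branches, plus the centre loss on PSFN features.
train_hmpi_joint <- function(model, train, valid) {
  spec <- model$spec
  ps <- spec$psfn
  x1 <- train$onehot
  x2 <- flatten_sp(train$sp)
  y <- train$labels
  eps <- if (spec$variant == "lsr") spec$epsilon else 0
  F1 <- ps$feature_dim
  with_seed(spec$seed + 1L, {
    st_stack <- adam_init_seq(model$psfn$stack)
    st_blocks <- lapply(model$dspn$blocks, adam_init_seq)
    st_head <- adam_init_seq(model$head)
    t_step <- 0L
    log <- list()
    best <- list(val_loss = Inf, stale = 0L, state = NULL)
    n <- length(y)
    for (epoch in seq_len(spec$epochs)) {
      batch_losses <- c()
      for (idx in minibatches(n, spec$batch_size)) {
        yb <- y[idx]
        fw1 <- seq_forward(model$psfn$stack, x1[, , idx, drop = FALSE], TRUE)
        model$psfn$stack <- fw1$layers
        fw2 <- dspn_forward(model$dspn, x2[, idx, drop = FALSE], TRUE)
        model$dspn$blocks <- fw2$blocks
        fused <- rbind(fw1$out, fw2$features)
        fwh <- seq_forward(model$head, fused, TRUE)
        xe <- xent_loss_grad(fwh$out, yb, eps)
        cl <- centre_loss_grad(fw1$out, yb, model$psfn$centres,
                               ps$lambda_centre)
        loss <- xe$loss + cl$loss
        if (!is.finite(loss)) {
          abort(paste0("training diverged (non-finite loss) at epoch ", epoch))
        }
        batch_losses <- c(batch_losses, loss)
        bwh <- seq_backward(model$head, fwh$caches, xe$dlogits)
        df1 <- bwh$dx[seq_len(F1), , drop = FALSE] + cl$df
        df2 <- bwh$dx[-seq_len(F1), , drop = FALSE]
        bw1 <- seq_backward(model$psfn$stack, fw1$caches, df1)
        bw2 <- dspn_backward(model$dspn, fw2, df2)
        t_step <- t_step + 1L
        up <- adam_step_seq(model$psfn$stack, bw1$grads, st_stack, t_step,
                            spec$learning_rate)
        model$psfn$stack <- up$layers; st_stack <- up$state
        for (i in seq_len(7L)) {
          up <- adam_step_seq(model$dspn$blocks[[i]], bw2$grads[[i]],
                              st_blocks[[i]], t_step, spec$learning_rate)
          model$dspn$blocks[[i]] <- up$layers
          st_blocks[[i]] <- up$state
        }
        up <- adam_step_seq(model$head, bwh$grads, st_head, t_step,
                            spec$learning_rate)
        model$head <- up$layers; st_head <- up$state
        if (ps$lambda_centre > 0) {
          model$psfn$centres <- update_centres(model$psfn$centres, fw1$out,
                                               yb, ps$centre_alpha)
        }
      }
      row <- tibble(epoch = epoch, loss = mean(batch_losses),
                    val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(valid)) {
        p <- t(hmpi_probs(model, valid))
        yv <- valid$labels
        row$val_loss <- -mean(log(pmax(p[cbind(yv, seq_along(yv))], PROB_FLOOR)))
        row$val_acc <- mean(max.col(t(p)) == yv)
        if (row$val_loss < best$val_loss - 1e-6) {
          best$val_loss <- row$val_loss; best$stale <- 0L
          best$state <- list(stack = model$psfn$stack,
                             centres = model$psfn$centres,
                             blocks = model$dspn$blocks, head = model$head)
        } else best$stale <- best$stale + 1L
      }
      log[[epoch]] <- row
      if (!is.null(valid) && best$stale >= spec$patience) break
    }
    if (!is.null(best$state)) {
      model$psfn$stack <- best$state$stack
      model$psfn$centres <- best$state$centres
      model$dspn$blocks <- best$state$blocks
      model$head <- best$state$head
    }
    model$psfn$trained <- TRUE
    model$dspn$trained <- TRUE
    model$psfn$classes <- model$dspn$classes <- train$classes
    list(model = model, log = dplyr::bind_rows(log))
  })
}

#' Train the HMPIat imbalance-aware variant
#'
#' The raw one-hot encoding cannot be interpolated meaningfully, so
#' synthetic minority samples are generated by transfer at the second
#' convolution block of the pretrained PSFN. Pipeline: (1) pretrain both
#' branches on the imbalanced data; (2) for every training sample,
#' extract the full second-block feature maps (flattened) together with
#' the DSPN structural features; (3) run ADASYN ([adasyn_augment()]) in
#' that joint space, so each synthetic sample receives a consistent
#' convex combination of both representations; (4) push the synthetic
#' second-block maps through the transferred upper PSFN layers (block 3
#' onward, frozen) to obtain sequence feature vectors, concatenate with
#' the structural part, and train a fresh fusion head on the augmented
#' feature set with cross-entropy. Real samples therefore keep exactly
#' the base HMPI representation; the variant differs only by the
#' resampling. Synthetic rows are counted in the log attributes.
#'
#' @inheritParams train_hmpi
#' @return The trained model (prediction uses the standard fused
#'   representation with the ADASYN-trained head).
#' @export
run_hmpiat <- function(model, train, valid = NULL) {
  stopifnot(inherits(model, "hmpi_model"))
  spec <- model$spec
  check_encoded(train, c("onehot", "sp"), spec$psfn$input_length,
                spec$num_classes)
  model$classes <- train$classes
  model$psfn <- train_psfn(model$psfn, train, valid)
  model$dspn <- train_dspn(model$dspn, train, valid)
  maps <- psfn_block2_maps(model$psfn, train)      # filters x L x n
  md <- dim(maps)
  b2 <- maps
  dim(b2) <- c(md[1L] * md[2L], md[3L])
  S <- extract_structural_features(model$dspn, train)
  X <- cbind(t(b2), S)                             # n x (filters*L + 128)
  aug <- adasyn_augment(X, train$classes[train$labels],
                        k = spec$adasyn_k,
                        balance_level = spec$adasyn_balance,
                        seed = spec$seed + 7L)
  y_aug <- match(aug$labels, train$classes)
  # transfer: synthetic block-2 maps go through the frozen upper PSFN
  b2_dim <- md[1L] * md[2L]
  maps_aug <- t(aug$features[, seq_len(b2_dim), drop = FALSE])
  dim(maps_aug) <- c(md[1L], md[2L], ncol(maps_aug))
  f_seq <- psfn_features_from_block2(model$psfn, maps_aug)
  X_head <- rbind(f_seq, t(aug$features[, -seq_len(b2_dim), drop = FALSE]))
  head <- with_seed(spec$seed + 3L, {
    list(nn_dense(nrow(X_head), spec$head_hidden), nn_relu(),
         nn_dense(spec$head_hidden, spec$num_classes))
  })
  Xv <- NULL
  if (!is.null(valid)) {
    Xv <- t(cbind(extract_features(model$psfn, valid, "feature_layer"),
                  extract_structural_features(model$dspn, valid)))
  }
  fit <- train_feature_head(head, X_head, y_aug, epsilon = 0,
                            lr = spec$learning_rate,
                            batch_size = spec$batch_size,
                            epochs = spec$epochs, patience = spec$patience,
                            seed = spec$seed,
                            x_valid = Xv,
                            y_valid = if (!is.null(valid)) valid$labels)
  model$at_head <- fit$layers
  log <- fit$log
  attr(log, "regime") <- "adasyn_transfer"
  attr(log, "n_synthetic") <- sum(aug$synthetic)
  attr(log, "class_counts") <- table(aug$labels)
  model$log <- new_training_log(log, "hmpi/at")
  model$mode <- "at"
  model$trained <- TRUE
  model
}

# Adam training of a small dense stack on fixed feature vectors.
train_feature_head <- function(layers, x, y, epsilon = 0, lr = 1e-3,
                               batch_size = 64L, epochs = 50L, patience = 5L,
                               seed = 1L, x_valid = NULL, y_valid = NULL) {
  with_seed(seed + 2L, {
    state <- adam_init_seq(layers)
    t_step <- 0L
    log <- list()
    best <- list(val_loss = Inf, stale = 0L, layers = NULL)
    n <- ncol(x)
    for (epoch in seq_len(epochs)) {
      batch_losses <- c()
      for (idx in minibatches(n, batch_size)) {
        fw <- seq_forward(layers, x[, idx, drop = FALSE], TRUE)
        layers <- fw$layers
        xe <- xent_loss_grad(fw$out, y[idx], epsilon)
        if (!is.finite(xe$loss)) {
          abort(paste0("training diverged (non-finite loss) at epoch ", epoch))
        }
        batch_losses <- c(batch_losses, xe$loss)
        bw <- seq_backward(layers, fw$caches, xe$dlogits)
        t_step <- t_step + 1L
        up <- adam_step_seq(layers, bw$grads, state, t_step, lr)
        layers <- up$layers
        state <- up$state
      }
      row <- tibble(epoch = epoch, loss = mean(batch_losses),
                    val_loss = NA_real_, val_acc = NA_real_)
      if (!is.null(x_valid)) {
        p <- softmax_batch(seq_forward(layers, x_valid, FALSE)$out)
        row$val_loss <- -mean(log(pmax(p[cbind(y_valid, seq_along(y_valid))],
                                       PROB_FLOOR)))
        row$val_acc <- mean(max.col(t(p)) == y_valid)
        if (row$val_loss < best$val_loss - 1e-6) {
          best$val_loss <- row$val_loss; best$stale <- 0L
          best$layers <- layers
        } else best$stale <- best$stale + 1L
      }
      log[[epoch]] <- row
      if (!is.null(x_valid) && best$stale >= patience) break
    }
    if (!is.null(best$layers)) layers <- best$layers
    list(layers = layers, log = dplyr::bind_rows(log))
  })
}

hmpi_probs <- function(model, data) {
  head <- if (identical(model$mode, "at") && !is.null(model$at_head)) {
    model$at_head
  } else {
    model$head
  }
  X <- t(cbind(extract_features(model$psfn, data, "feature_layer"),
               extract_structural_features(model$dspn, data)))
  t(softmax_batch(seq_forward(head, X, FALSE)$out))
}

#' Predicted class probabilities from the hybrid model
#'
#' @param object A trained `hmpi_model`.
#' @param data An encoded dataset carrying both encodings.
#' @param ... Unused.
#' @return An `n x K` probability matrix (rows sum to 1; columns named
#'   by class).
#' @export
predict.hmpi_model <- function(object, data, ...) {
  if (!object$trained) abort("model is not trained")
  check_encoded(data, c("onehot", "sp"), object$spec$psfn$input_length)
  p <- hmpi_probs(object, data)
  colnames(p) <- object$classes
  p
}

#' Class labels from a probability matrix
#'
#' @param probs An `n x K` probability matrix with class column names.
#' @return Character vector of argmax labels.
#' @export
predicted_classes <- function(probs) {
  cls <- colnames(probs) %||% as.character(seq_len(ncol(probs)))
  cls[max.col(probs)]
}

#' @export
print.hmpi_model <- function(x, ...) {
  s <- x$spec
  cat("<hmpi_model> ", if (x$trained) "trained" else "untrained",
      "; variant '", s$variant, "', regime '", s$regime, "'\n", sep = "")
  cat("  fused width ", s$fused_dim, " -> Dense(", s$head_hidden, ") -> ",
      s$num_classes, "-way softmax\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy hmpi_model
tidy.hmpi_model <- function(x, ...) {
  if (is.null(x$log)) abort("model has no training log; train it first")
  x$log
}

#' @export
#' @method glance hmpi_model
glance.hmpi_model <- function(x, ...) {
  tibble(
    trained = x$trained,
    variant = x$spec$variant,
    regime = if (is.null(x$log)) NA_character_ else attr(x$log, "regime"),
    epochs_run = if (is.null(x$log)) 0L else nrow(x$log),
    final_val_acc = if (is.null(x$log)) NA_real_ else x$log$val_acc[nrow(x$log)],
    fused_dim = x$spec$fused_dim
  )
}
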