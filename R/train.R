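# Mini-batch training with best-validation-epoch checkpointing.

#' Training configuration presets
#'
#' `kind = "cnn"`: learning rate 0.001, Adam, 100 epochs, no schedule.
#' `kind = "stgcn"`: learning rate 0.1, SGD with momentum 0.9, cosine
#' annealing, weight decay 0.001, 200 epochs. Cross-entropy loss in both.
#' Any field can be overridden (epochs are routinely reduced for desk-scale
#' runs; the presets are the full-scale protocol).
#'
#' @param kind `"cnn"` or `"stgcn"`.
#' @param ... Field overrides (`lr`, `optimizer`, `momentum`,
#'   `weight_decay`, `schedule`, `epochs`, `batch_size`, `seed`).
#' @return A `train_config` list.
#' @export
train_config <- function(kind = c("cnn", "stgcn"), ...) {
  kind <- match.arg(kind)
  cfg <- if (kind == "cnn") {
    list(kind = "cnn", lr = 0.001, optimizer = "adam", momentum = 0.9,
         weight_decay = 0, schedule = "none", epochs = 100,
         loss = "cross_entropy", batch_size = 16, seed = 0)
  } else {
    list(kind = "stgcn", lr = 0.1, optimizer = "sgd", momentum = 0.9,
         weight_decay = 0.001, schedule = "cosine_annealing", epochs = 200,
         loss = "cross_entropy", batch_size = 16, seed = 0)
  }
  over <- list(...)
  sg_assert(all(names(over) %in% names(cfg)),
            sprintf("unknown train_config fields: %s",
                    paste(setdiff(names(over), names(cfg)), collapse = ", ")))
  cfg[names(over)] <- over
  class(cfg) <- "train_config"
  cfg
}

slice_batch <- function(x, idx) x[, , , idx, drop = FALSE]

model_forward <- function(model, x, train = TRUE) {
  if (!is.null(model$to_internal)) x <- model$to_internal(x)
  model$root$forward(x, train)
}

#' Fit a classifier
#'
#' Mini-batch SGD/Adam training on channel-first 4-D input (last dimension
#' = samples). When a validation set is supplied, the parameters from the
#' epoch with the highest validation accuracy are restored at the end
#' (ties broken toward the earlier epoch). Fully deterministic given
#' `config$seed`.
#'
#' @param model A `sarcogait_model`.
#' @param x 4-D feature array, samples in the last dimension.
#' @param y Integer class labels in 1..num_classes.
#' @param config A [train_config()].
#' @param x_val,y_val Optional validation set.
#' @param augment Optional function applied to each training batch (uses
#'   R's RNG, hence seeded).
#' @param verbose Print per-epoch progress.
#' @return Invisibly, a history list (`train_loss`, `val_acc`,
#'   `best_epoch`).
#' @export
fit_classifier <- function(model, x, y, config, x_val = NULL, y_val = NULL,
                           augment = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "sarcogait_model"))
  n <- dim(x)[4]
  sg_assert(length(y) == n, "one label per sample")
  layers <- collect_layers(model$root)
  opt <- make_optimizer(config$optimizer, lr = config$lr,
                        momentum = config$momentum,
                        weight_decay = config$weight_decay)
  hist <- list(train_loss = numeric(0), val_acc = numeric(0), best_epoch = NA)
  best_acc <- -Inf
  best_snap <- NULL
  with_seed(derive_seed(config$seed, "fit"), {
    for (epoch in seq_len(config$epochs)) {
      lr_now <- if (config$schedule == "cosine_annealing") {
        cosine_lr(config$lr, epoch, config$epochs)
      } else config$lr
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- slice_batch(x, idx)
        if (!is.null(augment)) xb <- augment(xb)
        logits <- model_forward(model, xb, train = TRUE)
        ce <- cross_entropy(logits, y[idx])
        if (!is.finite(ce$loss)) {
          sg_abort(sprintf("non-finite loss at epoch %d (lr %.4g)", epoch, lr_now),
                   "sarcogait_training_diverged")
        }
        model$root$backward(ce$dlogits)
        opt$step(layers, lr = lr_now)
        losses <- c(losses, ce$loss)
      }
      hist$train_loss <- c(hist$train_loss, mean(losses))
      if (!is.null(x_val)) {
        acc <- mean(predict_classes(model, x_val) == y_val)
        hist$val_acc <- c(hist$val_acc, acc)
        if (acc > best_acc) {
          best_acc <- acc
          best_snap <- snapshot_params(model$root)
          hist$best_epoch <- epoch
        }
      }
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val %.3f", epoch,
                        mean(losses),
                        if (length(hist$val_acc)) utils::tail(hist$val_acc, 1) else NA))
      }
    }
  })
  if (!is.null(best_snap)) restore_params(model$root, best_snap)
  invisible(hist)
}

#' Predict hard class labels
#'
#' @param model A `sarcogait_model`.
#' @param x 4-D feature array, samples last.
#' @param batch_size Evaluation batch size.
#' @return Integer labels in 1..num_classes.
#' @export
predict_classes <- function(model, x, batch_size = 64) {
  n <- dim(x)[4]
  out <- integer(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    logits <- model_forward(model, slice_batch(x, idx), train = FALSE)
    out[idx] <- apply(logits, 2, which.max)
  }
  out
}
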