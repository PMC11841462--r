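#' Training procedure settings
#'
#' Adam with categorical cross-entropy (plus the branches' ridge penalties),
#' best-weight checkpointing on validation accuracy, learning-rate reduction
#' when the validation loss plateaus, and early stopping. Defaults follow
#' the reference training recipe: learning rate 0.001, batch size 64, up to
#' 1000 epochs with early-stopping patience 300.
#'
#' @param learning_rate Adam step size.
#' @param batch_size trials per gradient step.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without a validation-accuracy
#'   improvement before stopping; defaults to 300, capped at `max_epochs`.
#' @param lr_reduce_patience epochs without a validation-loss improvement
#'   before the learning rate is multiplied by `lr_reduce_factor`.
#' @param lr_reduce_factor multiplicative learning-rate reduction factor.
#' @param validation_fraction fraction of the training set held out for
#'   validation when no validation set is supplied (stratified).
#' @param seed RNG seed for shuffling, dropout and attention sampling.
#' @param verbose print one line per epoch.
#' @return A `train_control` list.
#' @export
train_control <- function(learning_rate = 0.001, batch_size = 64,
                          max_epochs = 1000, early_stop_patience = NULL,
                          lr_reduce_patience = 20, lr_reduce_factor = 0.9,
                          validation_fraction = 0.2, seed = 1,
                          verbose = FALSE) {
  if (is.null(early_stop_patience))
    early_stop_patience <- min(300, max_epochs)
  ck(learning_rate > 0, "invalid learning_rate")
  ck(batch_size >= 1, "invalid batch_size")
  ck(max_epochs >= 1, "invalid max_epochs")
  ck(early_stop_patience >= 1 && early_stop_patience <= max_epochs,
     "invalid early_stop_patience: must be in [1, max_epochs]")
  ck(lr_reduce_patience >= 1, "invalid lr_reduce_patience")
  ck(lr_reduce_factor > 0 && lr_reduce_factor <= 1, "invalid lr_reduce_factor")
  ck(validation_fraction > 0 && validation_fraction < 1,
     "invalid validation_fraction")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 lr_reduce_factor = lr_reduce_factor,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_control")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    gk <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk * gk
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

eval_on <- function(model, data, batch_size = 64) {
  probs <- predict(model, data, type = "prob", batch_size = batch_size)
  idx <- cbind(seq_len(nrow(probs)), data$labels + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  acc <- mean(max.col(probs, ties.method = "first") - 1L == data$labels)
  list(loss = loss, acc = acc)
}

#' Train a built model
#'
#' Runs mini-batch Adam on categorical cross-entropy plus the convolutional
#' branches' ridge penalties. During training the attention block samples
#' its stochastic pooling; validation metrics use deterministic
#' expectation-mode pooling and batch-norm running statistics. Weights are
#' checkpointed whenever validation accuracy improves and the best
#' checkpoint is restored at the end.
#'
#' @param model a [build_ciacnet()] model.
#' @param train training [eeg_trialset()].
#' @param valid optional validation [eeg_trialset()]; when `NULL` a
#'   stratified `validation_fraction` of `train` is held out.
#' @param control a [train_control()].
#' @return An object of class `ciacnet_fit`: the trained `model` (best
#'   checkpoint restored), a per-epoch `history` data frame, `best_epoch`,
#'   `best_val_acc` and the elapsed `wall_time` in seconds.
#' @export
train_ciacnet <- function(model, train, valid = NULL,
                          control = train_control()) {
  ck(inherits(model, "ciacnet"), "model must come from build_ciacnet()")
  ck(inherits(train, "eeg_trialset"), "train must be an eeg_trialset")
  ck(inherits(control, "train_control"), "control must be a train_control")
  cfg <- model$config
  ck(max(train$labels) < cfg$n_classes,
     "training labels cover class ", max(train$labels),
     " but the model has ", cfg$n_classes, " classes")
  if (is.null(valid)) {
    sp <- split_trialset(train, 1 - control$validation_fraction,
                         seed = control$seed)
    train <- sp$train
    valid <- sp$test
  }
  ck(inherits(valid, "eeg_trialset"), "valid must be an eeg_trialset")
  ck(all(dim(valid$signals)[2:3] == dim(train$signals)[2:3]),
     "train and valid shapes differ")
  ck(max(valid$labels) < cfg$n_classes, "validation labels exceed n_classes")

  set.seed(control$seed)
  t0 <- proc.time()[["elapsed"]]
  params <- get_params(model)
  opt <- adam_init(params)
  lr <- control$learning_rate
  n <- n_trials(train)
  hist <- data.frame()
  best_acc <- -Inf; best_loss <- Inf
  best_params <- params; best_bn <- get_bn_state(model); best_epoch <- 0L
  acc_wait <- 0L; loss_wait <- 0L

  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (ix in split(ord, ceiling(seq_along(ord) / control$batch_size))) {
      xb <- aperm(train$signals[ix, , , drop = FALSE], c(3, 2, 1))
      fw <- ciacnet_forward(model, xb, training = TRUE, keep_cache = TRUE)
      model <- fw$model
      sm <- softmax_ce(fw$logits, train$labels[ix])
      ep_loss <- ep_loss + (sm$loss + ridge_penalty(model)) * length(ix)
      ep_correct <- ep_correct +
        sum(max.col(t(sm$probs), ties.method = "first") - 1L ==
              train$labels[ix])
      grads <- ciacnet_backward(model, fw$cache, sm$dlogits)
      upd <- adam_step(params, grads, opt, lr)
      params <- upd$params
      opt <- upd$state
      model <- set_params(model, params)
    }
    vm <- eval_on(model, valid, control$batch_size)
    hist <- rbind(hist, data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss / n,
      train_acc = ep_correct / n, val_loss = vm$loss, val_acc = vm$acc))
    if (control$verbose)
      message(sprintf("epoch %3d lr %.2e loss %.4f acc %.3f | val %.4f %.3f",
                      epoch, lr, ep_loss / n, ep_correct / n, vm$loss, vm$acc))
    if (vm$acc > best_acc) {
      best_acc <- vm$acc
      best_params <- params
      best_bn <- get_bn_state(model)
      best_epoch <- epoch
      acc_wait <- 0L
    } else {
      acc_wait <- acc_wait + 1L
    }
    if (vm$loss < best_loss - 1e-12) {
      best_loss <- vm$loss
      loss_wait <- 0L
    } else {
      loss_wait <- loss_wait + 1L
      if (loss_wait >= control$lr_reduce_patience) {
        lr <- lr * control$lr_reduce_factor
        loss_wait <- 0L
      }
    }
    if (acc_wait >= control$early_stop_patience) break
  }
  model <- set_params(model, best_params)
  model <- set_bn_state(model, best_bn)
  structure(list(model = model, history = hist, best_epoch = best_epoch,
                 best_val_acc = best_acc, control = control,
                 wall_time = proc.time()[["elapsed"]] - t0),
            class = "ciacnet_fit")
}

#' Fit the classifier to a trial set
#'
#' One-call interface: Z-score normalization statistics are fit on the
#' training set and applied to every set, the model is built with fresh
#' weights and trained with [train_ciacnet()].
#'
#' @param train training [eeg_trialset()].
#' @param valid optional validation [eeg_trialset()].
#' @param config optional [ciacnet_config()]; defaults to the standard
#'   architecture sized from the data.
#' @param control a [train_control()].
#' @param normalize apply per-channel Z-score normalization (default TRUE);
#'   the statistics are stored in the fit and re-applied by `predict`.
#' @param seed seed for weight initialization (the training seed lives in
#'   `control`).
#' @return A `ciacnet_fit` (see [train_ciacnet()]) additionally carrying the
#'   normalization statistics.
#' @examples
#' \donttest{
#' x <- generate_mi(synth_config(n_trials_per_class = 6, n_channels = 4,
#'                               n_samples = 256, seed = 3))
#' sp <- split_trialset(x, 2 / 3, seed = 1)
#' fit <- ciacnet(sp$train, config = ciacnet_config(4, 256, 4),
#'                control = train_control(max_epochs = 2, batch_size = 8))
#' predict(fit, sp$test, type = "class")
#' }
#' @export
ciacnet <- function(train, valid = NULL, config = NULL,
                    control = train_control(), normalize = TRUE, seed = 1) {
  ck(inherits(train, "eeg_trialset"), "train must be an eeg_trialset")
  d <- dim(train$signals)
  if (is.null(config))
    config <- ciacnet_config(n_channels = d[2], n_samples = d[3],
                             n_classes = train$n_classes)
  stats <- NULL
  if (normalize) {
    stats <- zscore_fit(train)
    train <- zscore_apply(train, stats)
    if (!is.null(valid)) valid <- zscore_apply(valid, stats)
  }
  model <- build_ciacnet(config, seed = seed)
  fit <- train_ciacnet(model, train, valid, control)
  fit$zscore <- stats
  fit
}

#' @export
predict.ciacnet_fit <- function(object, newdata, type = c("prob", "class"),
                                ...) {
  if (!is.null(object$zscore))
    newdata <- zscore_apply(newdata, object$zscore)
  predict(object$model, newdata, type = match.arg(type), ...)
}

#' @export
print.ciacnet_fit <- function(x, ...) {
  cat(sprintf(
    "<ciacnet_fit> %d epochs run, best epoch %d (val accuracy %.3f), %.1f s\n",
    nrow(x$history), x$best_epoch, x$best_val_acc, x$wall_time))
  print(x$model)
  invisible(x)
}

#' @export
summary.ciacnet_fit <- function(object, ...) {
  print(object)
  cat("\nLast epochs:\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' @export
coef.ciacnet_fit <- function(object, ...) get_params(object$model)

#' @export
plot.ciacnet_fit <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "accuracy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}
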