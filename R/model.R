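#' Full architecture configuration
#'
#' Assembles the hyperparameters of the complete classifier: two parallel
#' convolutional branches (CV1, CV2) fed by the raw `C x T` trial, an
#' attention block on the CV1 output, a dilated causal TCN fed by the
#' attention output, and a dense softmax head over the concatenation of the
#' attention output (skip), the TCN output and the CV2 output.
#'
#' @param n_channels EEG channels `C`.
#' @param n_samples samples per trial `T`.
#' @param n_classes number of classes `N`.
#' @param cv1,cv2 [conv_branch_config()]s for the two branches.
#' @param attention an [attention_config()].
#' @param tcn a [tcn_config()].
#' @param remove character subset of `c("CV2", "IAT", "TC")` naming blocks
#'   to excise (ablation variants); removing IAT routes the CV1 output
#'   directly to the TCN and the skip, removing TC or CV2 drops that branch
#'   from the concatenation.
#' @return A `ciacnet_config` list.
#' @export
ciacnet_config <- function(n_channels = 22, n_samples = 1125, n_classes = 4,
                           cv1 = cv1_config(), cv2 = cv2_config(),
                           attention = attention_config(),
                           tcn = tcn_config(), remove = character(0)) {
  ck(n_channels >= 1, "invalid n_channels")
  ck(n_samples >= 1, "invalid n_samples")
  ck(n_classes >= 2, "invalid n_classes")
  remove <- toupper(remove)
  bad <- setdiff(remove, c("CV2", "IAT", "TC"))
  if (length(bad))
    stop("invalid variant: cannot remove block(s) ",
         paste(bad, collapse = ", "),
         " (removable blocks are CV2, IAT, TC; the CV1 branch always remains)",
         call. = FALSE)
  structure(list(n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 cv1 = cv1, cv2 = cv2, attention = attention, tcn = tcn,
                 remove = remove),
            class = "ciacnet_config")
}

#' Ablation variant of a configuration
#'
#' Returns the configuration with the given blocks excised and the
#' concatenation re-wired, keeping everything else identical. All eight
#' subsets of `{CV2, IAT, TC}` are valid; the CV1 branch can never be
#' removed.
#'
#' @param config a [ciacnet_config()].
#' @param remove character subset of `c("CV2", "IAT", "TC")`.
#' @return A `ciacnet_config` for the variant.
#' @export
make_variant <- function(config, remove = character(0)) {
  ck(inherits(config, "ciacnet_config"), "config must be a ciacnet_config")
  ciacnet_config(config$n_channels, config$n_samples, config$n_classes,
                 config$cv1, config$cv2, config$attention, config$tcn,
                 remove = remove)
}

#' Build the classifier with freshly initialized weights
#'
#' @param config a [ciacnet_config()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `ciacnet` (untrained). Use
#'   [train_ciacnet()] or the one-call [ciacnet()] to fit it, and
#'   [predict.ciacnet()] for inference.
#' @examples
#' m <- build_ciacnet(ciacnet_config(n_channels = 4, n_samples = 128,
#'                                   n_classes = 2))
#' model_parameter_count(m)
#' @export
build_ciacnet <- function(config, seed = NULL) {
  ck(inherits(config, "ciacnet_config"), "config must be a ciacnet_config")
  if (!is.null(seed)) set.seed(seed)
  has <- function(b) !(b %in% config$remove)
  cv1 <- build_branch(config$cv1, config$n_channels, config$n_samples)
  len <- unname(cv1$out_shape["length"])
  f1 <- unname(cv1$out_shape["filters"])
  model <- list(config = config, cv1 = cv1,
                has_cv2 = has("CV2"), has_iat = has("IAT"), has_tc = has("TC"),
                seq_len = len)
  feat <- f1 * len                               # skip branch (IAT or CV1)
  if (model$has_iat) model$iat <- build_iat(config$attention, f1)
  if (model$has_tc) {
    model$tcn <- build_tcn(config$tcn, f1)
    feat <- feat + config$tcn$filters * len
  }
  if (model$has_cv2) {
    cv2 <- build_branch(config$cv2, config$n_channels, config$n_samples)
    ck(unname(cv2$out_shape["length"]) == len,
       "construction error at concatenation: CV1 and CV2 output lengths differ")
    model$cv2 <- cv2
    feat <- feat + unname(cv2$out_shape["filters"]) * len
  }
  model$feature_length <- as.integer(feat)
  model$head <- list(W = glorot(config$n_classes, feat, fan_in = feat),
                     b = rep(0, config$n_classes))
  class(model) <- "ciacnet"
  model
}

# (L, N, C) activation -> (L*C, N) per-trial feature columns
flatten_lnc <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1, 3, 2))
  dim(m) <- c(d[1] * d[3], d[2])
  m
}

unflatten_lnc <- function(m, L, C) {
  N <- ncol(m)
  dim(m) <- c(L, C, N)
  aperm(m, c(1, 3, 2))
}

# Forward pass over a batch. xb: (T, C, N). Returns logits (N_classes x N),
# the updated model (batch-norm running stats) and optionally the cache.
ciacnet_forward <- function(model, xb, training = FALSE, keep_cache = FALSE,
                            pool_mode = NULL) {
  if (is.null(pool_mode))
    pool_mode <- if (training) "sample" else
      model$config$attention$inference_pool_mode
  len <- model$seq_len
  cv1f <- branch_forward(model$cv1, xb, training, keep_intermediates = keep_cache)
  model$cv1 <- cv1f$branch
  skip <- cv1f$out                                 # (len, N, F2)
  cache <- list(cv1 = cv1f$cache, shapes = cv1f$shapes)
  if (model$has_iat) {
    iatf <- iat_forward(skip, model$iat, pool_mode, H = 1L, W = len,
                        keep_cache = keep_cache)
    cache$iat <- iatf$cache
    skip <- iatf$out
  }
  feats <- flatten_lnc(skip)
  if (model$has_tc) {
    tcf <- tcn_forward(model$tcn, skip, training, keep_cache = keep_cache)
    model$tcn <- tcf$tcn
    cache$tcn <- tcf$cache
    cache$tc_dim <- dim(tcf$out)
    feats <- rbind(feats, flatten_lnc(tcf$out))
  }
  if (model$has_cv2) {
    cv2f <- branch_forward(model$cv2, xb, training,
                           keep_intermediates = keep_cache)
    model$cv2 <- cv2f$branch
    cache$cv2 <- cv2f$cache
    cache$cv2_dim <- dim(cv2f$out)
    feats <- rbind(feats, flatten_lnc(cv2f$out))
  }
  logits <- model$head$W %*% feats + model$head$b
  cache$feats <- feats
  cache$skip_dim <- dim(if (model$has_iat) cache$iat$Fb else skip)
  res <- list(logits = logits, model = model)
  if (keep_cache) res$cache <- cache
  res
}

# Backward pass; dlogits: (N_classes x N). Returns a flat named gradient
# list matching get_params(model).
ciacnet_backward <- function(model, cache, dlogits) {
  g <- list()
  g[["head.W"]] <- tcrossprod(dlogits, cache$feats)
  g[["head.b"]] <- rowSums(dlogits)
  dfeats <- crossprod(model$head$W, dlogits)
  len <- model$seq_len
  f1 <- unname(model$cv1$out_shape["filters"])
  n_skip <- f1 * len
  dskip <- unflatten_lnc(dfeats[seq_len(n_skip), , drop = FALSE], len, f1)
  ofs <- n_skip
  if (model$has_tc) {
    n_tc <- model$config$tcn$filters * len
    dtc <- unflatten_lnc(dfeats[ofs + seq_len(n_tc), , drop = FALSE], len,
                         model$config$tcn$filters)
    ofs <- ofs + n_tc
    tb <- tcn_backward(model$tcn, cache$tcn, dtc)
    dskip <- dskip + tb$dx
    for (l in seq_along(tb$blocks)) {
      for (nm in names(tb$blocks[[l]])) {
        key <- sub("^bn([12])_(gamma|beta)$", "bn\\1.\\2", nm)
        g[[paste0("tcn.b", l, ".", key)]] <- tb$blocks[[l]][[nm]]
      }
    }
  }
  if (model$has_cv2) {
    f4 <- unname(model$cv2$out_shape["filters"])
    dcv2 <- unflatten_lnc(dfeats[ofs + seq_len(f4 * len), , drop = FALSE],
                          len, f4)
    bb <- branch_backward(model$cv2, cache$cv2, dcv2)
    for (nm in names(bb))
      g[[paste0("cv2.", sub("_", ".", nm))]] <- bb[[nm]]
  }
  if (model$has_iat) {
    ib <- iat_backward(dskip, model$iat, cache$iat)
    g[["iat.W0"]] <- ib$dW0; g[["iat.W1"]] <- ib$dW1
    g[["iat.Ws"]] <- ib$dWs; g[["iat.bs"]] <- ib$dbs
    dskip <- ib$dF
  }
  bb <- branch_backward(model$cv1, cache$cv1, dskip)
  for (nm in names(bb))
    g[[paste0("cv1.", sub("_", ".", nm))]] <- bb[[nm]]
  g
}

# --- flat parameter access (used by the optimizer and checkpointing) -------

branch_param_list <- function(br, prefix) {
  out <- list()
  out[[paste0(prefix, ".Wt")]] <- br$params$Wt
  out[[paste0(prefix, ".Wd")]] <- br$params$Wd
  out[[paste0(prefix, ".Wp")]] <- br$params$Wp
  for (b in c("bn1", "bn2", "bn3")) {
    out[[paste0(prefix, ".", b, ".gamma")]] <- br[[b]]$gamma
    out[[paste0(prefix, ".", b, ".beta")]] <- br[[b]]$beta
  }
  out
}

get_params <- function(model) {
  out <- branch_param_list(model$cv1, "cv1")
  if (model$has_cv2) out <- c(out, branch_param_list(model$cv2, "cv2"))
  if (model$has_iat)
    out <- c(out, list(iat.W0 = model$iat$params$W0,
                       iat.W1 = model$iat$params$W1,
                       iat.Ws = model$iat$params$Ws,
                       iat.bs = model$iat$params$bs))
  if (model$has_tc) {
    for (l in seq_along(model$tcn$blocks)) {
      bl <- model$tcn$blocks[[l]]
      pre <- paste0("tcn.b", l, ".")
      out[[paste0(pre, "W1")]] <- bl$W1
      out[[paste0(pre, "W2")]] <- bl$W2
      out[[paste0(pre, "bn1.gamma")]] <- bl$bn1$gamma
      out[[paste0(pre, "bn1.beta")]] <- bl$bn1$beta
      out[[paste0(pre, "bn2.gamma")]] <- bl$bn2$gamma
      out[[paste0(pre, "bn2.beta")]] <- bl$bn2$beta
      if (!is.null(bl$Wp)) {
        out[[paste0(pre, "Wp")]] <- bl$Wp
        out[[paste0(pre, "bp")]] <- bl$bp
      }
    }
  }
  out[["head.W"]] <- model$head$W
  out[["head.b"]] <- model$head$b
  out
}

set_branch_params <- function(br, lst, prefix) {
  br$params$Wt <- lst[[paste0(prefix, ".Wt")]]
  br$params$Wd <- lst[[paste0(prefix, ".Wd")]]
  br$params$Wp <- lst[[paste0(prefix, ".Wp")]]
  for (b in c("bn1", "bn2", "bn3")) {
    br[[b]]$gamma <- lst[[paste0(prefix, ".", b, ".gamma")]]
    br[[b]]$beta <- lst[[paste0(prefix, ".", b, ".beta")]]
  }
  br
}

set_params <- function(model, lst) {
  model$cv1 <- set_branch_params(model$cv1, lst, "cv1")
  if (model$has_cv2) model$cv2 <- set_branch_params(model$cv2, lst, "cv2")
  if (model$has_iat) {
    model$iat$params$W0 <- lst$iat.W0
    model$iat$params$W1 <- lst$iat.W1
    model$iat$params$Ws <- lst$iat.Ws
    model$iat$params$bs <- lst$iat.bs
  }
  if (model$has_tc) {
    for (l in seq_along(model$tcn$blocks)) {
      pre <- paste0("tcn.b", l, ".")
      bl <- model$tcn$blocks[[l]]
      bl$W1 <- lst[[paste0(pre, "W1")]]
      bl$W2 <- lst[[paste0(pre, "W2")]]
      bl$bn1$gamma <- lst[[paste0(pre, "bn1.gamma")]]
      bl$bn1$beta <- lst[[paste0(pre, "bn1.beta")]]
      bl$bn2$gamma <- lst[[paste0(pre, "bn2.gamma")]]
      bl$bn2$beta <- lst[[paste0(pre, "bn2.beta")]]
      if (!is.null(bl$Wp)) {
        bl$Wp <- lst[[paste0(pre, "Wp")]]
        bl$bp <- lst[[paste0(pre, "bp")]]
      }
      model$tcn$blocks[[l]] <- bl
    }
  }
  model$head$W <- lst$head.W
  model$head$b <- lst$head.b
  model
}

# Batch-norm running statistics (model state, not trainable parameters).
get_bn_state <- function(model) {
  pick <- function(bn) list(run_mean = bn$run_mean, run_var = bn$run_var)
  st <- list(cv1 = lapply(model$cv1[c("bn1", "bn2", "bn3")], pick))
  if (model$has_cv2)
    st$cv2 <- lapply(model$cv2[c("bn1", "bn2", "bn3")], pick)
  if (model$has_tc)
    st$tcn <- lapply(model$tcn$blocks, function(bl)
      list(bn1 = pick(bl$bn1), bn2 = pick(bl$bn2)))
  st
}

set_bn_state <- function(model, st) {
  put <- function(bn, s) { bn$run_mean <- s$run_mean; bn$run_var <- s$run_var; bn }
  for (b in c("bn1", "bn2", "bn3"))
    model$cv1[[b]] <- put(model$cv1[[b]], st$cv1[[b]])
  if (model$has_cv2)
    for (b in c("bn1", "bn2", "bn3"))
      model$cv2[[b]] <- put(model$cv2[[b]], st$cv2[[b]])
  if (model$has_tc)
    for (l in seq_along(model$tcn$blocks)) {
      model$tcn$blocks[[l]]$bn1 <- put(model$tcn$blocks[[l]]$bn1,
                                       st$tcn[[l]]$bn1)
      model$tcn$blocks[[l]]$bn2 <- put(model$tcn$blocks[[l]]$bn2,
                                       st$tcn[[l]]$bn2)
    }
  model
}

#' Number of trainable parameters
#'
#' @param model a [build_ciacnet()] model (trained or not).
#' @return Integer count of trainable weights (batch-norm running statistics
#'   excluded).
#' @export
model_parameter_count <- function(model) {
  ck(inherits(model, "ciacnet"), "model must be a ciacnet")
  sum(vapply(get_params(model), length, 0L))
}

ridge_penalty <- function(model) {
  p <- branch_l2_penalty(model$cv1)
  if (model$has_cv2) p <- p + branch_l2_penalty(model$cv2)
  p
}

#' Per-layer shape table
#'
#' Runs one trial through the network and tabulates every stage's output
#' shape; the dense-head feature length is the sum of the flattened skip,
#' TCN and CV2 branch outputs.
#'
#' @param model a `ciacnet` model.
#' @return A `data.frame` with columns `layer` and `shape`.
#' @export
model_shapes <- function(model) {
  ck(inherits(model, "ciacnet"), "model must be a ciacnet")
  cfg <- model$config
  xb <- array(0, c(cfg$n_samples, cfg$n_channels, 1L))
  fw <- ciacnet_forward(model, xb, training = FALSE, keep_cache = TRUE,
                        pool_mode = "expectation")
  sh <- fw$cache$shapes
  fmt <- function(d) paste(d[-2], collapse = " x ")   # drop batch dim
  rows <- data.frame(
    layer = c("input (C x T)",
              "cv1 temporal conv", "cv1 depthwise conv", "cv1 avg pool 1",
              "cv1 pointwise conv", "cv1 avg pool 2 (branch output)"),
    shape = c(paste(cfg$n_channels, "x", cfg$n_samples),
              fmt(sh$temporal_conv), fmt(sh$depthwise), fmt(sh$pool1),
              fmt(sh$pointwise_conv), fmt(sh$pool2)),
    stringsAsFactors = FALSE)
  if (model$has_iat)
    rows <- rbind(rows, data.frame(layer = "attention (gated feature map)",
                                   shape = fmt(fw$cache$skip_dim)))
  if (model$has_tc)
    rows <- rbind(rows, data.frame(layer = "tcn output",
                                   shape = fmt(fw$cache$tc_dim)))
  if (model$has_cv2)
    rows <- rbind(rows, data.frame(layer = "cv2 branch output",
                                   shape = fmt(fw$cache$cv2_dim)))
  rbind(rows,
        data.frame(layer = "concatenated features",
                   shape = as.character(model$feature_length)),
        data.frame(layer = "dense + softmax",
                   shape = as.character(cfg$n_classes)))
}

#' Predict class probabilities or labels
#'
#' Inference uses batch-norm running statistics, no dropout, and
#' deterministic expectation-mode stochastic pooling unless `pool_mode =
#' "sample"` is forced.
#'
#' @param object a `ciacnet` model (typically trained).
#' @param newdata an [eeg_trialset()] with the model's channel and sample
#'   counts.
#' @param type `"prob"` for an `n x N` probability matrix, `"class"` for
#'   0-based argmax labels.
#' @param pool_mode attention pooling mode, default the configured
#'   inference mode.
#' @param batch_size trials per forward chunk.
#' @param ... unused.
#' @return Probability matrix or integer label vector.
#' @export
predict.ciacnet <- function(object, newdata, type = c("prob", "class"),
                            pool_mode = NULL, batch_size = 64, ...) {
  type <- match.arg(type)
  ck(inherits(newdata, "eeg_trialset"), "newdata must be an eeg_trialset")
  d <- dim(newdata$signals)
  ck(d[2] == object$config$n_channels && d[3] == object$config$n_samples,
     "newdata shape (", d[2], " x ", d[3], ") does not match the model (",
     object$config$n_channels, " x ", object$config$n_samples, ")")
  probs <- matrix(0, d[1], object$config$n_classes)
  for (ix in split(seq_len(d[1]), ceiling(seq_len(d[1]) / batch_size))) {
    xb <- aperm(newdata$signals[ix, , , drop = FALSE], c(3, 2, 1))
    fw <- ciacnet_forward(object, xb, training = FALSE,
                          pool_mode = pool_mode)
    probs[ix, ] <- t(softmax_cols(fw$logits))
  }
  if (type == "prob") probs else max.col(probs, ties.method = "first") - 1L
}

#' @export
print.ciacnet <- function(x, ...) {
  cfg <- x$config
  blocks <- c("CV1", if (x$has_iat) "IAT", if (x$has_tc) "TC",
              if (x$has_cv2) "CV2")
  cat(sprintf("<ciacnet> %d ch x %d samples -> %d classes | blocks: %s\n",
              cfg$n_channels, cfg$n_samples, cfg$n_classes,
              paste(blocks, collapse = "+")))
  cat(sprintf("  features into head: %d | trainable parameters: %d\n",
              x$feature_length, model_parameter_count(x)))
  if (x$has_tc)
    cat(sprintf("  tcn receptive field: %d (sequence length %d)\n",
                receptive_field(cfg$tcn$kernel_size, cfg$tcn$n_blocks),
                x$seq_len))
  invisible(x)
}

#' @export
summary.ciacnet <- function(object, ...) {
  print(object)
  tb <- model_shapes(object)
  cat("\nPer-layer output shapes (one trial):\n")
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-34s %s\n", tb$layer[i], tb$shape[i]))
  if (object$has_tc) {
    rfs <- receptive_field(object$config$tcn$kernel_size,
                           object$config$tcn$n_blocks)
    if (rfs < object$seq_len)
      cat(sprintf("  warning: TCN receptive field (%d) < sequence length (%d)\n",
                  rfs, object$seq_len))
  }
  invisible(tb)
}
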