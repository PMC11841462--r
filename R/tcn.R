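#' Temporal convolutional network configuration
#'
#' A stack of residual blocks of dilated causal convolutions. Block `l`
#' (1-based) uses dilation `2^(l-1)` in both of its convolutions; each
#' convolution is left-padded by `(kernel_size - 1) * dilation` zeros so the
#' output length equals the input length and no output depends on future
#' samples. Each convolution is followed by batch normalization, ELU and
#' dropout; the block input is added back (through a 1x1 projection when the
#' channel counts differ) and an ELU follows the sum.
#'
#' @param kernel_size causal kernel length `K_T`.
#' @param n_blocks number of residual blocks `L`.
#' @param filters convolution filter count per layer.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @return A `tcn_config` list.
#' @export
tcn_config <- function(kernel_size = 4, n_blocks = 2, filters = 32,
                       dropout_rate = 0.3) {
  ck(kernel_size >= 1, "invalid kernel_size: must be >= 1")
  ck(n_blocks >= 1, "invalid n_blocks: must be >= 1")
  ck(filters >= 1, "invalid filters: must be >= 1")
  ck(dropout_rate >= 0 && dropout_rate < 1,
     "invalid dropout_rate: must be in [0, 1)")
  structure(list(kernel_size = as.integer(kernel_size),
                 n_blocks = as.integer(n_blocks),
                 filters = as.integer(filters),
                 dropout_rate = dropout_rate),
            class = "tcn_config")
}

#' Receptive field size of the dilated causal TCN
#'
#' Closed form for the number of past time steps that influence one output
#' step when every residual block holds two causal convolutions of length
#' `kernel_size` and block `l` uses dilation `2^(l-1)`:
#' `1 + 2 * (kernel_size - 1) * (2^n_blocks - 1)`.
#'
#' @param kernel_size causal kernel length (`>= 1`).
#' @param n_blocks number of residual blocks (`>= 1`).
#' @return Integer receptive field size in time steps.
#' @examples
#' receptive_field(4, 2)  # 19
#' @export
receptive_field <- function(kernel_size, n_blocks) {
  ck(kernel_size >= 1, "kernel_size must be >= 1")
  ck(n_blocks >= 1, "n_blocks must be >= 1")
  as.integer(1 + 2 * (kernel_size - 1) * (2^n_blocks - 1))
}

#' Build a TCN for a given input channel count
#'
#' @param config a [tcn_config()].
#' @param in_channels channels of the incoming sequence.
#' @return An object of class `tcn` holding per-block weights and
#'   batch-norm state. Output sequences have `config$filters` channels and
#'   the input length.
#' @export
build_tcn <- function(config, in_channels) {
  ck(inherits(config, "tcn_config"), "config must be a tcn_config")
  ck(in_channels >= 1, "in_channels must be >= 1")
  K <- config$kernel_size; Fn <- config$filters
  blocks <- vector("list", config$n_blocks)
  cin <- as.integer(in_channels)
  for (l in seq_len(config$n_blocks)) {
    bl <- list(dilation = 2L^(l - 1L),
               W1 = glorot(Fn, cin * K, fan_in = cin * K),
               bn1 = bn_init(Fn),
               W2 = glorot(Fn, Fn * K, fan_in = Fn * K),
               bn2 = bn_init(Fn))
    if (cin != Fn) {
      bl$Wp <- glorot(Fn, cin, fan_in = cin)
      bl$bp <- rep(0, Fn)
    }
    blocks[[l]] <- bl
    cin <- Fn
  }
  structure(list(config = config, in_channels = as.integer(in_channels),
                 blocks = blocks),
            class = "tcn")
}

#' Run a TCN forward
#'
#' @param tcn a [build_tcn()] object.
#' @param x numeric array `(L, n, in_channels)` (time, batch, channel).
#' @param training logical; batch statistics and dropout when `TRUE`.
#' @param keep_cache keep activations for the backward pass.
#' @return List with `out` (array `(L, n, filters)`), updated `tcn`, and
#'   optionally `cache`.
#' @export
tcn_forward <- function(tcn, x, training = FALSE, keep_cache = FALSE) {
  cfg <- tcn$config
  K <- cfg$kernel_size
  caches <- vector("list", cfg$n_blocks)
  h <- x
  for (l in seq_len(cfg$n_blocks)) {
    bl <- tcn$blocks[[l]]
    padL <- (K - 1L) * bl$dilation
    c1 <- conv1d_forward(h, bl$W1, NULL, padL, 0L, bl$dilation)
    b1 <- bn_forward(c1, bl$bn1, training, need_xhat = keep_cache)
    e1 <- elu(b1$out)
    d1 <- dropout_forward(e1, cfg$dropout_rate, training)
    c2 <- conv1d_forward(d1$out, bl$W2, NULL, padL, 0L, bl$dilation)
    b2 <- bn_forward(c2, bl$bn2, training, need_xhat = keep_cache)
    e2 <- elu(b2$out)
    d2 <- dropout_forward(e2, cfg$dropout_rate, training)
    if (is.null(bl$Wp)) {
      res <- h
    } else {
      res <- conv1d_forward(h, bl$Wp, bl$bp, 0L, 0L, 1L)
    }
    out <- elu(d2$out + res)
    tcn$blocks[[l]]$bn1 <- b1$bn
    tcn$blocks[[l]]$bn2 <- b2$bn
    if (keep_cache)
      caches[[l]] <- list(x_in = h, b1 = b1$cache, e1 = e1, mask1 = d1$mask,
                          c2_in = d1$out, b2 = b2$cache, e2 = e2,
                          mask2 = d2$mask, out = out)
    h <- out
  }
  res <- list(out = h, tcn = tcn)
  if (keep_cache) res$cache <- caches
  res
}

# Backward pass; returns dx and per-block parameter gradients.
tcn_backward <- function(tcn, cache, dout) {
  cfg <- tcn$config
  K <- cfg$kernel_size
  grads <- vector("list", cfg$n_blocks)
  g <- dout
  for (l in rev(seq_len(cfg$n_blocks))) {
    bl <- tcn$blocks[[l]]
    cc <- cache[[l]]
    padL <- (K - 1L) * bl$dilation
    dsum <- mul_elu_grad(g, cc$out)
    # main path
    gm <- dropout_backward(dsum, cc$mask2)
    gm <- mul_elu_grad(gm, cc$e2)
    bb2 <- bn_backward(gm, bl$bn2, cc$b2)
    cb2 <- conv1d_backward(cc$c2_in, bl$W2, bb2$dx, padL, 0L, bl$dilation)
    gm <- dropout_backward(cb2$dx, cc$mask1)
    gm <- mul_elu_grad(gm, cc$e1)
    bb1 <- bn_backward(gm, bl$bn1, cc$b1)
    cb1 <- conv1d_backward(cc$x_in, bl$W1, bb1$dx, padL, 0L, bl$dilation)
    dx <- cb1$dx
    # residual path
    gb <- list(W1 = cb1$dw, W2 = cb2$dw,
               bn1_gamma = bb1$dgamma, bn1_beta = bb1$dbeta,
               bn2_gamma = bb2$dgamma, bn2_beta = bb2$dbeta)
    if (is.null(bl$Wp)) {
      dx <- dx + dsum
    } else {
      cbp <- conv1d_backward(cc$x_in, bl$Wp, dsum, 0L, 0L, 1L)
      dx <- dx + cbp$dx
      gb$Wp <- cbp$dw
      gb$bp <- cbp$db
    }
    grads[[l]] <- gb
    g <- dx
  }
  list(dx = g, blocks = grads)
}
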