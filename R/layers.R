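# Layer primitives with manual forward/backward passes.
#
# Activation layout convention: a batch of feature maps is a numeric array
# of dimension (L, B, C) = (time, batch, feature map). The electrode axis of
# the raw input is folded into B for the first temporal convolution (whose
# kernel is 1 x K and has a single input map) and handled explicitly by the
# depthwise layer.

conv1d_forward <- function(x, w, bias = NULL, pad_left, pad_right,
                           dilation = 1L) {
  cin <- dim(x)[3]
  k <- ncol(w) / cin
  .conv1d_fwd(x, dim(x), w, if (is.null(bias)) numeric(0) else bias,
              as.integer(k), as.integer(pad_left), as.integer(pad_right),
              as.integer(dilation))
}

conv1d_backward <- function(x, w, dy, pad_left, pad_right, dilation = 1L,
                            need_dx = TRUE) {
  cin <- dim(x)[3]
  k <- ncol(w) / cin
  .conv1d_bwd(x, dim(x), w, dy, as.integer(k), as.integer(pad_left),
              as.integer(pad_right), as.integer(dilation), need_dx)
}

# "same" padding split for a kernel of length k (keras convention: the
# extra zero goes on the right for even k).
same_pad <- function(k, dilation = 1L) {
  span <- (k - 1L) * dilation
  c(left = span %/% 2L, right = span - span %/% 2L)
}

# --- batch normalization over the feature-map axis (3rd dim) --------------

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c))
}

bn_forward <- function(x, bn, training, need_xhat = TRUE, momentum = 0.9,
                       eps = 1e-5) {
  d <- dim(x)
  nb <- d[1] * d[2]
  if (training) {
    st <- .bn_stats(x, nb, d[3])
    mu <- st$mean
    v <- st$var
    bn$run_mean <- momentum * bn$run_mean + (1 - momentum) * mu
    bn$run_var <- momentum * bn$run_var + (1 - momentum) * v
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
  }
  ivar <- 1 / sqrt(v + eps)
  ap <- .bn_apply(x, nb, d[3], mu, ivar, bn$gamma, bn$beta, need_xhat)
  out <- ap$out
  dim(out) <- d
  list(out = out, bn = bn,
       cache = if (need_xhat)
         list(xhat = ap$xhat, ivar = ivar, nb = nb, train = training))
}

bn_backward <- function(dy, bn, cache) {
  d <- dim(dy)
  r <- .bn_bwd(dy, cache$xhat, cache$nb, d[3], bn$gamma, cache$ivar,
               cache$train)
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

# --- average pooling along the time axis (floor division, no padding) -----

avgpool_forward <- function(x, p) {
  d <- dim(x)
  l2 <- d[1] %/% p
  xt <- x[seq_len(l2 * p), , , drop = FALSE]
  out <- colMeans(matrix(xt, p))
  dim(out) <- c(l2, d[2], d[3])
  out
}

avgpool_backward <- function(dy, p, l_in) {
  d <- dim(dy)
  dx <- array(0, c(l_in, d[2], d[3]))
  exp_rows <- rep(as.vector(dy), each = p) / p
  dim(exp_rows) <- c(d[1] * p, d[2], d[3])
  dx[seq_len(d[1] * p), , ] <- exp_rows
  dx
}

# --- dropout (inverted scaling) -------------------------------------------

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(out = x * mask, mask = mask)
}

dropout_backward <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# --- softmax + categorical cross-entropy ----------------------------------

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# labels: 0-based integer vector; returns mean loss and gradient w.r.t.
# logits (N_classes x n).
softmax_ce <- function(logits, labels) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  idx <- cbind(labels + 1L, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}

# --- weight initialization -------------------------------------------------

glorot <- function(nrow, ncol, fan_in = ncol, fan_out = nrow) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}
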