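#' Configuration of one convolutional (CV) branch
#'
#' A CV branch is an EEGNet-lineage feature extractor of three convolutions:
#' a length-preserving temporal convolution (`1 x K_temporal`,
#' `F_temporal` filters), a depthwise spatial convolution over the full
#' electrode axis (`C x 1`, depth multiplier `D`, valid padding, collapsing
#' the electrode axis), and a length-preserving pointwise temporal
#' convolution (`1 x K_pointwise`, `F_pointwise` filters). Batch
#' normalization follows every convolution; ELU, average pooling
#' (`1 x pool_size`, floor division) and dropout follow the second and third
#' stages; an L2 (ridge) penalty is attached to every convolution's weights.
#'
#' `cv1_config()` and `cv2_config()` return the two default branches: 16
#' temporal filters with kernel 32 and 32 pointwise filters for CV1; 32
#' temporal filters with kernel 64 and 64 pointwise filters for CV2.
#'
#' @param F_temporal temporal filter count.
#' @param K_temporal temporal kernel length.
#' @param depth_multiplier depthwise multiplier `D`.
#' @param F_pointwise third-layer filter count.
#' @param K_pointwise third-layer kernel length.
#' @param pool_size average-pool length, applied twice.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param l2_coeff ridge penalty weight on convolution kernels.
#' @return A `conv_branch_config` list.
#' @export
conv_branch_config <- function(F_temporal = 16, K_temporal = 32,
                               depth_multiplier = 2, F_pointwise = 32,
                               K_pointwise = 16, pool_size = 8,
                               dropout_rate = 0.3, l2_coeff = 0.01) {
  for (f in c("F_temporal", "K_temporal", "depth_multiplier", "F_pointwise",
              "K_pointwise", "pool_size"))
    ck(get(f) >= 1, "invalid ", f, ": must be >= 1")
  ck(dropout_rate >= 0 && dropout_rate < 1,
     "invalid dropout_rate: must be in [0, 1)")
  ck(l2_coeff >= 0, "invalid l2_coeff: must be >= 0")
  structure(list(F_temporal = as.integer(F_temporal),
                 K_temporal = as.integer(K_temporal),
                 depth_multiplier = as.integer(depth_multiplier),
                 F_pointwise = as.integer(F_pointwise),
                 K_pointwise = as.integer(K_pointwise),
                 pool_size = as.integer(pool_size),
                 dropout_rate = dropout_rate, l2_coeff = l2_coeff),
            class = "conv_branch_config")
}

#' @rdname conv_branch_config
#' @export
cv1_config <- function(...) conv_branch_config(...)

#' @rdname conv_branch_config
#' @export
cv2_config <- function(...) {
  conv_branch_config(F_temporal = 32, K_temporal = 64, F_pointwise = 64, ...)
}

#' Temporal length after repeated average pooling
#'
#' Closed-form shape calculus of a CV branch: the temporal convolutions are
#' length-preserving, so the output length is the input length floor-divided
#' by the pool size once per pooling stage. With the defaults (pool 8,
#' applied twice) an 1125-sample trial yields 140 after the first pool and
#' 17 at the branch output.
#'
#' @param T_in input length in samples.
#' @param pool_size pooling factor.
#' @param n_pools number of pooling stages applied.
#' @return Integer output length.
#' @examples
#' out_len(1125, 8, 1)  # 140
#' out_len(1125, 8, 2)  # 17
#' @export
out_len <- function(T_in, pool_size, n_pools = 2) {
  ck(T_in >= 1, "T_in must be >= 1")
  ck(pool_size >= 1, "pool_size must be >= 1")
  l <- as.integer(T_in)
  for (i in seq_len(n_pools)) l <- l %/% as.integer(pool_size)
  l
}

#' Build a CV branch for a given input geometry
#'
#' Validates the geometry, initializes the weights (Glorot uniform kernels,
#' unit-gain batch norm) and returns a branch object whose forward pass is
#' run by [branch_forward()].
#'
#' @param config a [conv_branch_config()].
#' @param C number of EEG channels.
#' @param T_in samples per trial.
#' @return An object of class `conv_branch` carrying `params`, batch-norm
#'   state and the output shape (`F_pointwise x 1 x out_len`).
#' @export
build_branch <- function(config, C, T_in) {
  ck(inherits(config, "conv_branch_config"), "config must be a conv_branch_config")
  ck(C >= 1, "temporal conv layer: C must be >= 1")
  ck(T_in >= config$K_temporal,
     "temporal conv layer: T (", T_in, ") < kernel length (",
     config$K_temporal, ")")
  ck(out_len(T_in, config$pool_size, 2) >= 1,
     "pooling layers: input too short, branch output length would be 0")
  F1 <- config$F_temporal; D <- config$depth_multiplier
  Fp <- config$F_pointwise
  params <- list(
    Wt = glorot(F1, config$K_temporal, fan_in = config$K_temporal),
    Wd = array(runif(C * D * F1, -sqrt(6 / (C + D)), sqrt(6 / (C + D))),
               c(C, D, F1)),
    Wp = glorot(Fp, F1 * D * config$K_pointwise,
                fan_in = F1 * D * config$K_pointwise))
  structure(list(config = config, C = as.integer(C), T_in = as.integer(T_in),
                 params = params,
                 bn1 = bn_init(F1), bn2 = bn_init(F1 * D), bn3 = bn_init(Fp),
                 out_shape = c(filters = Fp, height = 1L,
                               length = out_len(T_in, config$pool_size, 2))),
            class = "conv_branch")
}

# depthwise spatial convolution: x (T, C*N, F1) viewed as (T, C, N, F1);
# out[t, n, (f-1)*D + d] = sum_h Wd[h, d, f] * x[t, h, n, f]
depthwise_forward <- function(x, Wd, C, N) {
  d <- dim(x)
  .depthwise_fwd(x, d[1], C, N, d[3], Wd, dim(Wd)[2])
}

depthwise_backward <- function(dy, Wd, x, C, N, T_len) {
  .depthwise_bwd(x, T_len, C, N, dim(Wd)[3], Wd, dim(Wd)[2], dy)
}

#' Run a CV branch forward
#'
#' @param branch a [build_branch()] object.
#' @param xb input batch, numeric array `(T, C, n)` (time, channel, trial).
#' @param training logical; enables batch statistics and dropout.
#' @param keep_intermediates keep per-stage activations (for shape
#'   inspection and the backward pass).
#' @return A list with `out` (array `(T_out, n, F_pointwise)`), the updated
#'   `branch` (batch-norm running statistics), and when requested `cache` /
#'   `shapes` of every stage.
#' @export
branch_forward <- function(branch, xb, training = FALSE,
                           keep_intermediates = FALSE) {
  cfg <- branch$config
  d <- dim(xb)
  ck(d[2] == branch$C, "branch built for ", branch$C, " channels, got ", d[2])
  T_len <- d[1]; N <- d[3]
  p <- branch$params
  x0 <- xb
  dim(x0) <- c(T_len, branch$C * N, 1L)
  pad <- same_pad(cfg$K_temporal)
  c1 <- conv1d_forward(x0, p$Wt, NULL, pad["left"], pad["right"])
  b1 <- bn_forward(c1, branch$bn1, training, need_xhat = keep_intermediates)
  dw_out <- depthwise_forward(b1$out, p$Wd, branch$C, N)
  b2 <- bn_forward(dw_out, branch$bn2, training, need_xhat = keep_intermediates)
  e2 <- elu(b2$out)
  p1 <- avgpool_forward(e2, cfg$pool_size)
  dr1 <- dropout_forward(p1, cfg$dropout_rate, training)
  pad2 <- same_pad(cfg$K_pointwise)
  c3 <- conv1d_forward(dr1$out, p$Wp, NULL, pad2["left"], pad2["right"])
  b3 <- bn_forward(c3, branch$bn3, training, need_xhat = keep_intermediates)
  e3 <- elu(b3$out)
  p2 <- avgpool_forward(e3, cfg$pool_size)
  dr2 <- dropout_forward(p2, cfg$dropout_rate, training)
  branch$bn1 <- b1$bn; branch$bn2 <- b2$bn; branch$bn3 <- b3$bn
  res <- list(out = dr2$out, branch = branch)
  if (keep_intermediates) {
    res$cache <- list(x0 = x0, b1 = b1$cache, x_dw = b1$out,
                      b2 = b2$cache, e2 = e2, p1_in_len = dim(e2)[1],
                      mask1 = dr1$mask, c3_in = dr1$out, b3 = b3$cache,
                      e3 = e3, p2_in_len = dim(e3)[1], mask2 = dr2$mask,
                      T_len = T_len, N = N)
    res$shapes <- list(
      input = d,
      temporal_conv = dim(c1), depthwise = dim(dw_out),
      pool1 = dim(p1), pointwise_conv = dim(c3), pool2 = dim(p2))
  }
  res
}

# Backward pass; returns parameter gradients (ridge included) and nothing
# for the raw input (the branch is the first trainable stage).
branch_backward <- function(branch, cache, dout) {
  cfg <- branch$config
  p <- branch$params
  g <- dropout_backward(dout, cache$mask2)
  g <- avgpool_backward(g, cfg$pool_size, cache$p2_in_len)
  g <- mul_elu_grad(g, cache$e3)
  bb3 <- bn_backward(g, branch$bn3, cache$b3)
  pad2 <- same_pad(cfg$K_pointwise)
  cb3 <- conv1d_backward(cache$c3_in, p$Wp, bb3$dx, pad2["left"],
                         pad2["right"])
  g <- dropout_backward(cb3$dx, cache$mask1)
  g <- avgpool_backward(g, cfg$pool_size, cache$p1_in_len)
  g <- mul_elu_grad(g, cache$e2)
  bb2 <- bn_backward(g, branch$bn2, cache$b2)
  ddw <- depthwise_backward(bb2$dx, p$Wd, cache$x_dw, branch$C, cache$N,
                            cache$T_len)
  bb1 <- bn_backward(ddw$dx, branch$bn1, cache$b1)
  pad <- same_pad(cfg$K_temporal)
  cb1 <- conv1d_backward(cache$x0, p$Wt, bb1$dx, pad["left"], pad["right"],
                         need_dx = FALSE)
  list(Wt = cb1$dw + 2 * cfg$l2_coeff * p$Wt,
       Wd = ddw$dWd + 2 * cfg$l2_coeff * p$Wd,
       Wp = cb3$dw + 2 * cfg$l2_coeff * p$Wp,
       bn1_gamma = bb1$dgamma, bn1_beta = bb1$dbeta,
       bn2_gamma = bb2$dgamma, bn2_beta = bb2$dbeta,
       bn3_gamma = bb3$dgamma, bn3_beta = bb3$dbeta)
}

branch_l2_penalty <- function(branch) {
  branch$config$l2_coeff * (sum(branch$params$Wt^2) +
                            sum(branch$params$Wd^2) +
                            sum(branch$params$Wp^2))
}
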