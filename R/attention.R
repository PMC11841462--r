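#' Stochastic pooling of an activation region
#'
#' Pools a region by probability rather than deterministically: activations
#' are clamped at zero, normalized to probabilities `p_i = a_i / sum(a_k)`,
#' and either one element is drawn from the multinomial over locations
#' (`"sample"`) or the probability-weighted mean `sum(p_i * a_i)` is
#' returned (`"expectation"`). A region that is all zero after clamping has
#' uniform probabilities and pools to 0.
#'
#' @param region numeric vector of activations (non-empty).
#' @param mode `"sample"` (stochastic, uses the R RNG) or `"expectation"`
#'   (deterministic).
#' @return A single pooled value.
#' @examples
#' stochastic_pool(c(1, 3), mode = "expectation")  # 0.25*1 + 0.75*3 = 2.5
#' @export
stochastic_pool <- function(region, mode = c("sample", "expectation")) {
  mode <- match.arg(mode)
  ck(length(region) >= 1, "stochastic_pool: empty pooling region")
  ck(all(is.finite(region)), "stochastic_pool: non-finite activations")
  b <- pmax(region, 0)
  s <- sum(b)
  if (s == 0) {
    if (mode == "expectation") return(0)
    return(b[sample.int(length(b), 1)])       # uniform fallback, value 0
  }
  p <- b / s
  if (mode == "expectation") sum(p * b) else b[sample.int(length(b), 1,
                                                          prob = p)]
}

#' Attention block configuration
#'
#' Channel-then-spatial attention in which the usual global average and max
#' pooling are joined by [stochastic_pool()] as a third descriptor. The
#' channel gate passes each pooled `C`-vector through a shared two-layer
#' perceptron (hidden width `ceiling(C / reduction_ratio)`, ReLU); the three
#' outputs are combined and squashed by a sigmoid. The spatial gate pools
#' across the channel axis at every position, concatenates the three maps
#' and convolves them with a `spatial_kernel x spatial_kernel` kernel
#' (length-preserving padding) before the sigmoid.
#'
#' @param reduction_ratio `r`; hidden width of the shared MLP is
#'   `ceiling(C / r)`.
#' @param spatial_kernel odd kernel size of the spatial-attention
#'   convolution.
#' @param channel_combine_mode `"sum_then_sigmoid"` sums the three MLP
#'   outputs and applies one sigmoid (gate in (0,1), the default);
#'   `"sum_of_sigmoids"` sums three sigmoids (gate in (0,3)).
#' @param inference_pool_mode pooling mode used when not training:
#'   `"expectation"` (deterministic, default) or `"sample"`.
#' @return An `attention_config` list.
#' @export
attention_config <- function(reduction_ratio = 8, spatial_kernel = 7,
                             channel_combine_mode = c("sum_then_sigmoid",
                                                      "sum_of_sigmoids"),
                             inference_pool_mode = c("expectation",
                                                     "sample")) {
  ck(reduction_ratio >= 1, "invalid reduction_ratio: must be >= 1")
  ck(spatial_kernel >= 1 && spatial_kernel %% 2 == 1,
     "invalid spatial_kernel: must be odd and >= 1")
  structure(list(reduction_ratio = as.integer(reduction_ratio),
                 spatial_kernel = as.integer(spatial_kernel),
                 channel_combine_mode = match.arg(channel_combine_mode),
                 inference_pool_mode = match.arg(inference_pool_mode)),
            class = "attention_config")
}

#' Build an attention block for feature maps with `C` channels
#'
#' @param config an [attention_config()].
#' @param C number of feature-map channels entering the block.
#' @return An object of class `iat_block` with the shared MLP weights
#'   (`W0`, `W1`), the spatial convolution kernel and bias.
#' @export
build_iat <- function(config, C) {
  ck(inherits(config, "attention_config"), "config must be an attention_config")
  ck(C >= 1, "C must be >= 1")
  hidden <- max(1L, as.integer(ceiling(C / config$reduction_ratio)))
  k <- config$spatial_kernel
  lim <- sqrt(6 / (3 * k * k + 1))
  structure(list(config = config, C = as.integer(C), hidden = hidden,
                 params = list(
                   W0 = glorot(hidden, C),
                   W1 = glorot(C, hidden),
                   Ws = array(runif(k * k * 3, -lim, lim), c(k, k, 3)),
                   bs = 0)),
            class = "iat_block")
}

# --- batched pooling helpers ------------------------------------------------
# m: (S, M) matrix, regions are columns. Returns pooled row vector(s) plus
# the bookkeeping the backward pass needs.

pool_cols <- function(m, mode) {
  S <- nrow(m); M <- ncol(m)
  avg <- colMeans(m)
  tm <- t(m)
  mx_idx <- max.col(tm, ties.method = "first")
  mx <- m[cbind(mx_idx, seq_len(M))]
  b <- pmax(m, 0)
  cs <- colSums(b)
  zero <- cs == 0
  if (mode == "expectation") {
    sto <- ifelse(zero, 0, colSums(b * b) / cs)
    sel <- NULL
  } else {
    bu <- b
    if (any(zero)) bu[, zero] <- 1
    csu <- colSums(bu)
    u <- runif(M) * csu
    cum <- apply(bu, 2, cumsum)
    sel <- max.col(t(cum >= rep(u, each = S)), ties.method = "first")
    sto <- b[cbind(sel, seq_len(M))]
  }
  list(avg = avg, max = mx, sto = sto, mx_idx = mx_idx, sel = sel,
       b = b, cs = cs, m = m)
}

# Backward of the three pools: given d(avg), d(max), d(sto) per column,
# return (S, M) gradient w.r.t. m.
pool_cols_backward <- function(pc, d_avg, d_max, d_sto, mode) {
  S <- nrow(pc$m); M <- ncol(pc$m)
  dm <- matrix(rep(d_avg / S, each = S), S, M)
  dm[cbind(pc$mx_idx, seq_len(M))] <-
    dm[cbind(pc$mx_idx, seq_len(M))] + d_max
  pos <- pc$m > 0
  if (mode == "expectation") {
    safe <- ifelse(pc$cs == 0, 1, pc$cs)
    v <- colSums(pc$b * pc$b) / safe
    grad <- sweep(2 * pc$b, 2, v, "-")
    grad <- sweep(grad, 2, safe, "/")
    grad[, pc$cs == 0] <- 0
    dm <- dm + grad * pos * rep(d_sto, each = S)
  } else {
    live <- pc$cs > 0
    idx <- cbind(pc$sel, seq_len(M))
    add <- d_sto * pos[idx] * live
    dm[idx] <- dm[idx] + add
  }
  dm
}

# --- channel attention (batched) -------------------------------------------
# Fb: (S, N, C); returns Mc (N, C).

mlp_forward <- function(s, W0, W1) {
  h <- pmax(s %*% t(W0), 0)
  list(h = h, o = h %*% t(W1))
}

ca_forward <- function(Fb, iat, mode) {
  d <- dim(Fb)
  S <- d[1]; N <- d[2]; C <- d[3]
  pc <- pool_cols(matrix(Fb, S, N * C), mode)
  s_avg <- matrix(pc$avg, N, C)
  s_max <- matrix(pc$max, N, C)
  s_sto <- matrix(pc$sto, N, C)
  p <- iat$params
  m_avg <- mlp_forward(s_avg, p$W0, p$W1)
  m_max <- mlp_forward(s_max, p$W0, p$W1)
  m_sto <- mlp_forward(s_sto, p$W0, p$W1)
  if (iat$config$channel_combine_mode == "sum_then_sigmoid") {
    z <- m_avg$o + m_max$o + m_sto$o
    Mc <- sigmoid(z)
    sig <- NULL
  } else {
    sig <- list(sigmoid(m_avg$o), sigmoid(m_max$o), sigmoid(m_sto$o))
    Mc <- sig[[1]] + sig[[2]] + sig[[3]]
  }
  list(Mc = Mc, cache = list(pc = pc, s = list(s_avg, s_max, s_sto),
                             mlp = list(m_avg, m_max, m_sto), sig = sig,
                             Mc = Mc, dims = d, mode = mode))
}

ca_backward <- function(dMc, iat, cache) {
  p <- iat$params
  if (iat$config$channel_combine_mode == "sum_then_sigmoid") {
    dz <- dMc * cache$Mc * (1 - cache$Mc)
    do_list <- list(dz, dz, dz)
  } else {
    do_list <- lapply(cache$sig, function(sg) dMc * sg * (1 - sg))
  }
  dW0 <- matrix(0, nrow(p$W0), ncol(p$W0))
  dW1 <- matrix(0, nrow(p$W1), ncol(p$W1))
  ds <- vector("list", 3)
  for (i in 1:3) {
    h <- cache$mlp[[i]]$h
    dh <- (do_list[[i]] %*% p$W1) * (h > 0)
    dW1 <- dW1 + crossprod(do_list[[i]], h)
    dW0 <- dW0 + crossprod(dh, cache$s[[i]])
    ds[[i]] <- dh %*% p$W0
  }
  d <- cache$dims
  dm <- pool_cols_backward(cache$pc, as.vector(ds[[1]]), as.vector(ds[[2]]),
                           as.vector(ds[[3]]), cache$mode)
  dim(dm) <- d
  list(dF = dm, dW0 = dW0, dW1 = dW1)
}

# --- pooling across channels per spatial position (rows of (S*N, C)) -------

pool_rows <- function(m, mode) {
  n <- nrow(m); C <- ncol(m)
  avg <- rowMeans(m)
  mx_idx <- max.col(m, ties.method = "first")
  mx <- m[cbind(seq_len(n), mx_idx)]
  b <- pmax(m, 0)
  rs <- rowSums(b)
  zero <- rs == 0
  if (mode == "expectation") {
    sto <- ifelse(zero, 0, rowSums(b * b) / rs)
    sel <- NULL
  } else {
    bu <- b
    if (any(zero)) bu[zero, ] <- 1
    rsu <- rowSums(bu)
    u <- runif(n) * rsu
    cum <- bu %*% upper.tri(diag(C), diag = TRUE)  # row-wise cumsum
    sel <- max.col(cum >= u, ties.method = "first")
    sto <- b[cbind(seq_len(n), sel)]
  }
  list(avg = avg, max = mx, sto = sto, mx_idx = mx_idx, sel = sel,
       b = b, rs = rs, m = m)
}

pool_rows_backward <- function(pr, d_avg, d_max, d_sto, mode) {
  n <- nrow(pr$m); C <- ncol(pr$m)
  dm <- matrix(d_avg / C, n, C)
  ridx <- cbind(seq_len(n), pr$mx_idx)
  dm[ridx] <- dm[ridx] + d_max
  pos <- pr$m > 0
  if (mode == "expectation") {
    safe <- ifelse(pr$rs == 0, 1, pr$rs)
    v <- rowSums(pr$b * pr$b) / safe
    grad <- (2 * pr$b - v) / safe
    grad[pr$rs == 0, ] <- 0
    dm <- dm + grad * pos * d_sto
  } else {
    live <- pr$rs > 0
    sidx <- cbind(seq_len(n), pr$sel)
    dm[sidx] <- dm[sidx] + d_sto * pos[sidx] * live
  }
  dm
}

# --- spatial attention (batched) -------------------------------------------
# Fp: (S, N, C) with S = H * W; returns Ms (S, N).

conv2d_same <- function(P, Ws) {
  # P: (H, W, N, 3); Ws: (k, k, 3); length-preserving zero padding.
  d <- dim(P)
  k <- dim(Ws)[1]
  pad <- (k - 1) %/% 2
  Pp <- array(0, c(d[1] + k - 1, d[2] + k - 1, d[3], 3))
  Pp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- P
  out <- array(0, c(d[1], d[2], d[3]))
  for (i in seq_len(k)) for (j in seq_len(k)) for (c in 1:3) {
    win <- Pp[i - 1 + seq_len(d[1]), j - 1 + seq_len(d[2]), , c, drop = FALSE]
    dim(win) <- d[1:3]
    out <- out + Ws[i, j, c] * win
  }
  out
}

conv2d_same_backward <- function(dout, P, Ws) {
  d <- dim(P)
  k <- dim(Ws)[1]
  pad <- (k - 1) %/% 2
  Pp <- array(0, c(d[1] + k - 1, d[2] + k - 1, d[3], 3))
  Pp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- P
  dWs <- array(0, dim(Ws))
  dPp <- array(0, dim(Pp))
  for (i in seq_len(k)) for (j in seq_len(k)) for (c in 1:3) {
    win <- Pp[i - 1 + seq_len(d[1]), j - 1 + seq_len(d[2]), , c, drop = FALSE]
    dim(win) <- d[1:3]
    dWs[i, j, c] <- sum(win * dout)
    acc <- dPp[i - 1 + seq_len(d[1]), j - 1 + seq_len(d[2]), , c,
               drop = FALSE]
    dim(acc) <- d[1:3]
    dPp[i - 1 + seq_len(d[1]), j - 1 + seq_len(d[2]), , c] <-
      acc + Ws[i, j, c] * dout
  }
  list(dWs = dWs,
       dP = dPp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE])
}

sa_forward <- function(Fp, iat, mode, H, W) {
  d <- dim(Fp)
  S <- d[1]; N <- d[2]; C <- d[3]
  ck(H * W == S, "spatial attention: H*W must equal the spatial size")
  pr <- pool_rows(matrix(Fp, S * N, C), mode)
  P <- array(c(pr$avg, pr$max, pr$sto), c(H, W, N, 3))
  p <- iat$params
  z <- conv2d_same(P, p$Ws) + p$bs
  Ms <- sigmoid(z)
  dim(Ms) <- c(S, N)
  list(Ms = Ms, cache = list(pr = pr, P = P, z = z, Ms = Ms, dims = d,
                             H = H, W = W, mode = mode))
}

sa_backward <- function(dMs, iat, cache) {
  d <- cache$dims
  dz <- dMs * cache$Ms * (1 - cache$Ms)
  dim(dz) <- c(cache$H, cache$W, d[2])
  cb <- conv2d_same_backward(dz, cache$P, iat$params$Ws)
  dP <- cb$dP
  dim(dP) <- c(d[1] * d[2], 3)
  dm <- pool_rows_backward(cache$pr, dP[, 1], dP[, 2], dP[, 3], cache$mode)
  dim(dm) <- d
  list(dF = dm, dWs = cb$dWs, dbs = sum(dz))
}

# --- full attention block ---------------------------------------------------
# Fb: (S, N, C) batched feature maps.

iat_forward <- function(Fb, iat, mode, H = 1L, W = dim(Fb)[1],
                        keep_cache = FALSE) {
  d <- dim(Fb)
  S <- d[1]; N <- d[2]; C <- d[3]
  ca <- ca_forward(Fb, iat, mode)
  Mc_e <- rep(as.vector(ca$Mc), each = S)
  Fp <- Fb * Mc_e
  sa <- sa_forward(Fp, iat, mode, H, W)
  Ms_e <- rep(as.vector(sa$Ms), times = C)
  out <- Fp * Ms_e
  res <- list(out = out, Mc = ca$Mc, Ms = sa$Ms)
  if (keep_cache)
    res$cache <- list(Fb = Fb, Fp = Fp, ca = ca$cache, sa = sa$cache,
                      Mc_e = Mc_e, Ms_e = Ms_e, dims = d)
  res
}

iat_backward <- function(dout, iat, cache) {
  d <- cache$dims
  S <- d[1]; N <- d[2]; C <- d[3]
  dMs <- rowSums(matrix(cache$Fp * dout, S * N, C))
  dim(dMs) <- c(S, N)
  dFp <- dout * cache$Ms_e
  sab <- sa_backward(dMs, iat, cache$sa)
  dFp <- dFp + sab$dF
  dMc <- colSums(matrix(cache$Fb * dFp, S, N * C))
  dim(dMc) <- c(N, C)
  dFb <- dFp * cache$Mc_e
  cab <- ca_backward(dMc, iat, cache$ca)
  list(dF = dFb + cab$dF, dW0 = cab$dW0, dW1 = cab$dW1, dWs = sab$dWs,
       dbs = sab$dbs)
}

# --- single-feature-map wrappers (C x H x W, the field's convention) -------

fmap_to_batch <- function(f_map) {
  d <- dim(f_map)
  ck(length(d) == 3, "feature map must be a C x H x W array")
  b <- aperm(f_map, c(2, 3, 1))          # (H, W, C)
  dim(b) <- c(d[2] * d[3], 1L, d[1])     # (S, 1, C)
  b
}

batch_to_fmap <- function(b, C, H, W) {
  dim(b) <- c(H, W, C)
  aperm(b, c(3, 1, 2))
}

#' Channel attention map of a feature map
#'
#' Reduces a `C x H x W` feature map to a per-channel gate: global average,
#' max and stochastic pooling each produce a `C`-vector, each passes through
#' the shared two-layer perceptron, and the results are combined per the
#' block's `channel_combine_mode`.
#'
#' @param f_map numeric array `C x H x W`.
#' @param iat an [build_iat()] block with matching `C`.
#' @param mode pooling mode (`"expectation"` or `"sample"`); defaults to the
#'   block's inference mode.
#' @return Numeric array `C x 1 x 1` with the channel gate.
#' @export
channel_attention <- function(f_map, iat, mode = NULL) {
  ck(inherits(iat, "iat_block"), "iat must come from build_iat()")
  ck(dim(f_map)[1] == iat$C, "feature map has ", dim(f_map)[1],
     " channels, block built for ", iat$C)
  if (is.null(mode)) mode <- iat$config$inference_pool_mode
  ca <- ca_forward(fmap_to_batch(f_map), iat, mode)
  array(as.vector(ca$Mc), c(iat$C, 1L, 1L))
}

#' Spatial attention map of a feature map
#'
#' Pools across the channel axis at every spatial position (average, max,
#' stochastic), concatenates the three maps and convolves them with the
#' block's `k x k` kernel (length-preserving padding) before a sigmoid.
#'
#' @inheritParams channel_attention
#' @return Numeric array `1 x H x W` with the spatial gate in (0, 1).
#' @export
spatial_attention <- function(f_map, iat, mode = NULL) {
  ck(inherits(iat, "iat_block"), "iat must come from build_iat()")
  if (is.null(mode)) mode <- iat$config$inference_pool_mode
  d <- dim(f_map)
  sa <- sa_forward(fmap_to_batch(f_map), iat, mode, d[2], d[3])
  array(as.vector(sa$Ms), c(1L, d[2], d[3]))
}

#' Apply channel-then-spatial attention to a feature map
#'
#' Computes `F' = Mc * F` (channel gate broadcast over positions) followed
#' by `F'' = Ms * F'` (spatial gate broadcast over channels). The output has
#' the shape of the input; in the default `sum_then_sigmoid` mode both gates
#' lie in (0, 1), so the block is a contraction: `|F''| <= |F|` elementwise.
#'
#' @inheritParams channel_attention
#' @return Numeric array `C x H x W`, the gated feature map.
#' @export
apply_iat <- function(f_map, iat, mode = NULL) {
  ck(inherits(iat, "iat_block"), "iat must come from build_iat()")
  ck(dim(f_map)[1] == iat$C, "feature map has ", dim(f_map)[1],
     " channels, block built for ", iat$C)
  if (is.null(mode)) mode <- iat$config$inference_pool_mode
  d <- dim(f_map)
  r <- iat_forward(fmap_to_batch(f_map), iat, mode, H = d[2], W = d[3])
  batch_to_fmap(r$out, d[1], d[2], d[3])
}
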