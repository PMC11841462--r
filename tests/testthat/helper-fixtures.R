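# Shared helpers: tiny geometries keep every unit test fast; the
# full-size architecture is exercised in the acceptance suite.

tiny_trialset <- function(n_per_class = 3, C = 4, T_len = 64, N = 2,
                          seed = 1) {
  set.seed(seed)
  n <- n_per_class * N
  eeg_trialset(array(rnorm(n * C * T_len), c(n, C, T_len)),
               labels = rep(seq_len(N) - 1L, n_per_class), fs = 250)
}

tiny_config <- function(C = 3, T_len = 64, N = 2, dropout = 0, l2 = 0) {
  ciacnet_config(
    n_channels = C, n_samples = T_len, n_classes = N,
    cv1 = conv_branch_config(F_temporal = 2, K_temporal = 5,
                             depth_multiplier = 2, F_pointwise = 2,
                             K_pointwise = 3, pool_size = 2,
                             dropout_rate = dropout, l2_coeff = l2),
    cv2 = conv_branch_config(F_temporal = 2, K_temporal = 7,
                             depth_multiplier = 2, F_pointwise = 3,
                             K_pointwise = 3, pool_size = 2,
                             dropout_rate = dropout, l2_coeff = l2),
    attention = attention_config(reduction_ratio = 2, spatial_kernel = 3),
    tcn = tcn_config(kernel_size = 2, n_blocks = 2, filters = 3,
                     dropout_rate = dropout))
}

# band power of one channel via the periodogram, restricted to [lo, hi] Hz
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))^2 / n
  fr <- (seq_len(n) - 1) * fs / n
  keep <- fr >= lo & fr <= hi & fr <= fs / 2
  sum(sp[keep]) / n
}
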