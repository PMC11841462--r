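test_that("stochastic pooling follows the activation-proportional multinomial", {
  # degenerate distribution: all mass on the only positive element
  set.seed(1)
  expect_equal(stochastic_pool(c(0, 0, 0, 7), "sample"), 7)
  # uniform region pools to the common value in both modes
  expect_equal(stochastic_pool(c(5, 5, 5, 5), "expectation"), 5)
  expect_equal(stochastic_pool(c(5, 5, 5, 5), "sample"), 5)
  # probability-weighted mean
  expect_equal(stochastic_pool(c(1, 3), "expectation"), 2.5)
  # all-zero (after clamping) region
  expect_equal(stochastic_pool(c(0, -2, 0), "expectation"), 0)
  expect_equal(stochastic_pool(c(-1, -2), "sample"), 0)
  expect_error(stochastic_pool(numeric(0)), "empty")

  # expectation mode equals the exact sum(p_i * a_i) oracle
  set.seed(2)
  for (i in 1:20) {
    r <- rnorm(sample(1:8, 1))
    b <- pmax(r, 0)
    want <- if (sum(b) > 0) sum(b^2) / sum(b) else 0
    expect_equal(stochastic_pool(r, "expectation"), want)
  }
})

test_that("sample frequencies match the normalized-activation probabilities", {
  set.seed(7)
  draws <- vapply(1:1e5, function(i) stochastic_pool(c(1, 3), "sample"), 0)
  p3 <- mean(draws == 3)
  se <- sqrt(0.75 * 0.25 / 1e5)
  expect_lt(abs(p3 - 0.75), 3 * se)

  region <- c(1, 2, 3, 4)
  draws <- vapply(1:1e5, function(i) stochastic_pool(region, "sample"), 0)
  obs <- as.vector(table(factor(draws, levels = region)))
  gof <- chisq.test(obs, p = region / sum(region))
  expect_gt(gof$p.value, 0.001)
})

test_that("channel attention obeys the zero-weight contracts and a hand oracle", {
  iat <- build_iat(attention_config(reduction_ratio = 2), C = 2)
  f <- array(c(1.5, 0.5), c(2, 1, 1))
  iz <- iat
  iz$params$W0[] <- 0; iz$params$W1[] <- 0
  expect_equal(as.vector(channel_attention(f, iz)), c(0.5, 0.5))

  iz$config$channel_combine_mode <- "sum_of_sigmoids"
  expect_equal(as.vector(channel_attention(f, iz)), c(1.5, 1.5))

  # hand-computed oracle, C = 2, H = W = 1 (all three pools see one value)
  ih <- iat
  ih$params$W0 <- matrix(c(0.5, -0.25), 1, 2)
  ih$params$W1 <- matrix(c(1, 2), 2, 1)
  s <- c(1.5, 0.5)
  h <- max(0, 0.5 * 1.5 - 0.25 * 0.5)
  want <- 1 / (1 + exp(-3 * c(1 * h, 2 * h)))
  expect_equal(as.vector(channel_attention(f, ih, mode = "expectation")),
               want)
  expect_identical(dim(channel_attention(f, ih)), c(2L, 1L, 1L))
})

test_that("spatial attention matches a hand-computed convolution oracle", {
  cfg <- attention_config(reduction_ratio = 2, spatial_kernel = 3)
  iat <- build_iat(cfg, C = 2)
  f <- array(c(1, 2, 3, 4, 5, 6), c(2, 1, 3))   # C=2, H=1, W=3, positive

  iz <- iat
  iz$params$Ws[] <- 0; iz$params$bs <- 0
  expect_true(all(spatial_attention(f, iz) == 0.5))
  expect_identical(dim(spatial_attention(f, iz)), c(1L, 1L, 3L))

  # independent oracle: pool across channels, 3x3 same conv (H = 1 uses the
  # kernel's middle row), sigmoid
  avg <- apply(f, c(2, 3), mean)
  mx <- apply(f, c(2, 3), max)
  sto <- apply(f, c(2, 3), function(v) sum(v^2) / sum(v))
  P <- list(avg, mx, sto)
  Ws <- iat$params$Ws
  conv <- matrix(0, 1, 3)
  for (w in 1:3) for (dw in -1:1) {
    sw <- w + dw
    if (sw >= 1 && sw <= 3)
      for (c in 1:3) conv[1, w] <- conv[1, w] + Ws[2, dw + 2, c] * P[[c]][1, sw]
  }
  want <- 1 / (1 + exp(-(conv + iat$params$bs)))
  got <- spatial_attention(f, iat, mode = "expectation")
  expect_equal(as.vector(got), as.vector(want), tolerance = 1e-12)

  # single-channel map: the three pooled maps all equal the (positive) input
  f1 <- array(abs(rnorm(4)) + 0.1, c(1, 2, 2))
  f3 <- array(rep(as.vector(f1), each = 3), c(3, 2, 2))
  i1 <- build_iat(cfg, C = 1)
  i3 <- build_iat(cfg, C = 3)
  i3$params$Ws <- i1$params$Ws; i3$params$bs <- i1$params$bs
  expect_equal(spatial_attention(f1, i1, mode = "expectation"),
               spatial_attention(f3, i3, mode = "expectation"))
})

test_that("the composite block gates, annihilates zero and contracts", {
  set.seed(3)
  iat <- build_iat(attention_config(reduction_ratio = 4), C = 8)
  f <- array(rnorm(8 * 2 * 5), c(8, 2, 5))

  # consistency: apply_iat == Mc * F then Ms * (Mc * F), expectation mode
  mc <- channel_attention(f, iat, mode = "expectation")
  fp <- f * as.vector(mc)
  ms <- spatial_attention(fp, iat, mode = "expectation")
  want <- fp * rep(ms[1, , ], each = 8)
  expect_equal(apply_iat(f, iat, mode = "expectation"), want)

  # zero input stays zero for any weights
  expect_true(all(apply_iat(array(0, dim(f)), iat) == 0))

  # default (sum-then-sigmoid) gates lie in (0,1): elementwise contraction
  for (i in 1:100) {
    fr <- array(rnorm(6 * 2 * 3), c(6, 2, 3))
    ir <- build_iat(attention_config(reduction_ratio = 2), C = 6)
    out <- apply_iat(fr, ir, mode = "expectation")
    expect_true(all(abs(out) <= abs(fr) + 1e-12))
  }

  # sample mode is reproducible bit-for-bit under a fixed seed
  set.seed(99); a <- apply_iat(f, iat, mode = "sample")
  set.seed(99); b <- apply_iat(f, iat, mode = "sample")
  expect_identical(a, b)
})
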