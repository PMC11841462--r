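test_that("generator is reproducible, balanced and finite", {
  cfg <- synth_config(n_trials_per_class = 3, n_channels = 4, n_samples = 125,
                      n_classes = 4, seed = 7)
  a <- generate_mi(cfg)
  b <- generate_mi(cfg)
  expect_identical(a$signals, b$signals)        # bit-identical under the seed
  expect_identical(a$labels, b$labels)
  expect_true(all(is.finite(a$signals)))
  expect_equal(unname(tabulate(a$labels + 1, 4)), rep(3L, 4))

  expect_error(synth_config(erd_depth = 1.5), "erd_depth")
  expect_error(synth_config(rhythm_band = c(8, 200)), "rhythm_band")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
})

test_that("ERD attenuates band power on the class's target channels by (1-d)^2", {
  d <- 0.5
  cfg <- synth_config(n_trials_per_class = 6, n_channels = 4, n_samples = 500,
                      n_classes = 2, erd_depth = d, noise_sd = 0, seed = 2)
  x <- generate_mi(cfg)
  tgt <- mi_target_channels(0, 4, 2)
  oth <- setdiff(seq_len(4), tgt)
  cls0 <- which(x$labels == 0)
  bp <- function(tr, ch) band_power(x$signals[tr, ch, ], cfg$fs, 8, 13)
  p_mod <- mean(sapply(cls0, function(i) mean(sapply(tgt, bp, tr = i))))
  p_un <- mean(sapply(cls0, function(i) mean(sapply(oth, bp, tr = i))))
  expect_lt(abs(p_mod / p_un - (1 - d)^2), 0.05 * (1 - d)^2)
})

test_that("with erd_depth = 0 target-channel band power carries no class signal", {
  cfg <- synth_config(n_trials_per_class = 200, n_channels = 4,
                      n_samples = 250, n_classes = 2, erd_depth = 0,
                      noise_sd = 2, seed = 31)
  x <- generate_mi(cfg)
  ch <- mi_target_channels(0, 4, 2)[1]
  bp <- apply(x$signals[, ch, ], 1, band_power, fs = cfg$fs, lo = 8, hi = 13)
  tt <- t.test(bp[x$labels == 0], bp[x$labels == 1])
  expect_gt(tt$p.value, 0.01)                  # no-effect null not rejected
})

test_that("artifacts add sparse high-amplitude transients", {
  base <- synth_config(n_trials_per_class = 5, n_channels = 4,
                       n_samples = 250, n_classes = 2, noise_sd = 1,
                       artifact_rate = 0, seed = 5)
  with_art <- synth_config(n_trials_per_class = 5, n_channels = 4,
                           n_samples = 250, n_classes = 2, noise_sd = 1,
                           artifact_rate = 3, seed = 5)
  a <- generate_mi(base)
  b <- generate_mi(with_art)
  expect_gt(max(abs(b$signals)), max(abs(a$signals)))
  expect_true(all(is.finite(b$signals)))
})

test_that("stratified split conserves per-class counts and is disjoint", {
  x <- generate_mi(synth_config(n_trials_per_class = 100, n_channels = 4,
                                n_samples = 16, n_classes = 2, noise_sd = 1,
                                seed = 1))
  sp <- split_trialset(x, 0.5, seed = 2)
  expect_equal(unname(tabulate(sp$train$labels + 1, 2)), c(50L, 50L))
  expect_equal(unname(tabulate(sp$test$labels + 1, 2)), c(50L, 50L))
  # union equals input: per-class counts and total signal mass conserved
  expect_equal(dim(sp$train)[1] + dim(sp$test)[1], 200)
  expect_equal(sum(sp$train$signals) + sum(sp$test$signals), sum(x$signals))

  sp2 <- split_trialset(x, 0.5, seed = 3)
  expect_equal(unname(tabulate(sp2$train$labels + 1, 2)), c(50L, 50L))
  expect_false(identical(sp$train$signals, sp2$train$signals))

  expect_error(split_trialset(x, 0.001, seed = 1), "invalid split")
})

test_that("class separability grows with erd_depth (band-power centroid probe)", {
  acc_at <- function(depth, seed) {
    cfg <- synth_config(n_trials_per_class = 12, n_channels = 8,
                        n_samples = 250, n_classes = 4, erd_depth = depth,
                        noise_sd = 2, seed = seed)
    x <- generate_mi(cfg)
    feats <- log(t(apply(x$signals, 1, function(tr)
      apply(tr, 1, band_power, fs = cfg$fs, lo = 8, hi = 13))))
    # nearest-centroid on a held-out half
    set.seed(seed)
    tr <- sort(unlist(lapply(0:3, function(c)
      sample(which(x$labels == c), 6))))
    te <- setdiff(seq_len(48), tr)
    cent <- sapply(0:3, function(c) colMeans(feats[intersect(tr,
      which(x$labels == c)), , drop = FALSE]))
    pred <- apply(feats[te, ], 1, function(f)
      which.min(colSums((cent - f)^2)) - 1L)
    mean(pred == x$labels[te])
  }
  med <- sapply(c(0, 0.3, 0.6), function(d)
    median(sapply(1:5, function(s) acc_at(d, s))))
  expect_true(all(diff(med) >= 0))
})
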