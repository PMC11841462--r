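test_that("the default topology concatenates 2176 features", {
  m <- build_ciacnet(ciacnet_config(), seed = 1)
  expect_identical(m$feature_length, 2176L)          # 32*17 + 32*17 + 64*17
  expect_identical(m$seq_len, 17L)
  tb <- model_shapes(m)
  expect_true("2176" %in% tb$shape)
})

test_that("ablation variants re-wire the concatenation", {
  cfg <- ciacnet_config()
  len <- function(remove)
    build_ciacnet(make_variant(cfg, remove), seed = 1)$feature_length
  expect_identical(len(character(0)), 2176L)
  expect_identical(len("TC"), as.integer(32 * 17 + 64 * 17))
  expect_identical(len("CV2"), as.integer(32 * 17 + 32 * 17))
  expect_identical(len(c("CV2", "IAT", "TC")), as.integer(32 * 17))
  expect_error(make_variant(cfg, "CV1"), "invalid variant")
  # empty removal is the full model
  m0 <- build_ciacnet(cfg, seed = 2)
  m1 <- build_ciacnet(make_variant(cfg, character(0)), seed = 2)
  expect_identical(names(ciacnet:::get_params(m0)),
                   names(ciacnet:::get_params(m1)))
})

test_that("parameter count matches an independent layer-by-layer hand count", {
  cfg <- tiny_config()           # C=3, T=64, miniature filter counts
  m <- build_ciacnet(cfg, seed = 1)
  branch_count <- function(b, C) {
    b$F_temporal * b$K_temporal +                        # temporal kernel
      C * b$depth_multiplier * b$F_temporal +            # depthwise kernel
      b$F_pointwise * b$F_temporal * b$depth_multiplier * b$K_pointwise +
      2 * (b$F_temporal + b$F_temporal * b$depth_multiplier + b$F_pointwise)
  }
  C <- cfg$n_channels
  f2 <- cfg$cv1$F_pointwise                              # attention channels
  hidden <- ceiling(f2 / cfg$attention$reduction_ratio)
  iat_count <- hidden * f2 + f2 * hidden +
    3 * cfg$attention$spatial_kernel^2 + 1
  K <- cfg$tcn$kernel_size; Fn <- cfg$tcn$filters
  tcn_count <- (Fn * f2 * K + Fn * Fn * K + 4 * Fn + Fn * f2 + Fn) +  # block 1
    (Fn * Fn * K + Fn * Fn * K + 4 * Fn)                              # block 2
  len <- out_len(cfg$n_samples, cfg$cv1$pool_size, 2)
  feat <- f2 * len + Fn * len + cfg$cv2$F_pointwise * len
  head_count <- cfg$n_classes * feat + cfg$n_classes
  want <- branch_count(cfg$cv1, C) + branch_count(cfg$cv2, C) +
    iat_count + tcn_count + head_count
  expect_identical(model_parameter_count(m), as.integer(want))
})

test_that("predictions are proper, deterministic probabilities", {
  cfg <- tiny_config()
  m <- build_ciacnet(cfg, seed = 3)
  x <- tiny_trialset(n_per_class = 3, C = 3, T_len = 64, N = 2, seed = 8)
  p <- predict(m, x, type = "prob")
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p >= 0))
  expect_identical(p, predict(m, x, type = "prob"))   # expectation mode
  expect_identical(predict(m, x, type = "class"),
                   max.col(p, ties.method = "first") - 1L)

  # a duplicated trial yields identical rows
  dup <- eeg_trialset(x$signals[c(1, 1, 1), , ], rep(0L, 3), x$fs,
                      n_classes = 2)
  pd <- predict(m, dup, type = "prob")
  expect_equal(pd[1, ], pd[2, ])
  expect_equal(pd[1, ], pd[3, ])

  expect_error(predict(m, tiny_trialset(C = 5, T_len = 64)), "shape")
})

test_that("training checkpoints the best weights and stops on patience", {
  x <- tiny_trialset(n_per_class = 8, C = 3, T_len = 64, N = 2, seed = 2)
  sp <- split_trialset(x, 0.75, seed = 1)
  m <- build_ciacnet(tiny_config(dropout = 0.2), seed = 4)
  fit <- train_ciacnet(m, sp$train, sp$test,
                       control = train_control(max_epochs = 4, batch_size = 4,
                                               early_stop_patience = 4,
                                               seed = 5))
  expect_s3_class(fit, "ciacnet_fit")
  expect_identical(nrow(fit$history), 4L)
  expect_equal(fit$best_val_acc, max(fit$history$val_acc))
  # restored checkpoint reproduces the recorded best validation accuracy
  acc <- mean(predict(fit$model, sp$test, type = "class") == sp$test$labels)
  expect_equal(acc, fit$best_val_acc)

  # patience 1 with a constant validation metric stops at epoch 2
  m2 <- build_ciacnet(tiny_config(), seed = 4)
  frozen <- train_ciacnet(m2, sp$train, sp$test,
                          control = train_control(learning_rate = 1e-12,
                                                  max_epochs = 10,
                                                  batch_size = 4,
                                                  early_stop_patience = 1,
                                                  seed = 5))
  expect_identical(nrow(frozen$history), 2L)
})

test_that("every ablation variant constructs, trains one epoch and predicts", {
  x <- tiny_trialset(n_per_class = 4, C = 3, T_len = 64, N = 2, seed = 6)
  sp <- split_trialset(x, 0.5, seed = 1)
  removals <- list(character(0), "CV2", "IAT", "TC", c("CV2", "IAT"),
                   c("CV2", "TC"), c("IAT", "TC"), c("CV2", "IAT", "TC"))
  for (rm in removals) {
    m <- build_ciacnet(make_variant(tiny_config(), rm), seed = 1)
    fit <- train_ciacnet(m, sp$train, sp$test,
                         control = train_control(max_epochs = 1,
                                                 batch_size = 4, seed = 1))
    pred <- predict(fit, sp$test, type = "class")
    expect_identical(length(pred), 4L)
  }
})

test_that("class-count mismatches are rejected", {
  x <- tiny_trialset(n_per_class = 4, C = 3, T_len = 64, N = 2, seed = 6)
  bad <- eeg_trialset(x$signals, x$labels + 2L, x$fs, n_classes = 4)
  m <- build_ciacnet(tiny_config(N = 2), seed = 1)
  expect_error(train_ciacnet(m, bad, control = train_control(max_epochs = 1,
                                                             batch_size = 4)),
               "classes")
})
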