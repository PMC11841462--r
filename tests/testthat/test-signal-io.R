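test_that("trial-set construction enforces its invariants", {
  sig <- array(rnorm(2 * 3 * 10), c(2, 3, 10))
  x <- eeg_trialset(sig, c(0L, 1L), fs = 250)
  expect_s3_class(x, "eeg_trialset")
  expect_identical(dim(x), c(2L, 3L, 10L))
  expect_identical(x$n_classes, 2L)

  expect_error(eeg_trialset(sig, c(0L, 1L, 0L), fs = 250), "labels length")
  expect_error(eeg_trialset(sig, c(0L, 5L), fs = 250, n_classes = 2),
               "n_classes")
  sig[1] <- NA
  expect_error(eeg_trialset(sig, c(0L, 1L), fs = 250), "finite")
  expect_error(eeg_trialset(array(0, c(0, 3, 10)), integer(0), 250), "empty")
})

test_that("z-score statistics pool per channel over trials and time", {
  x <- eeg_trialset(array(c(1, 2, 3), c(1, 1, 3)), 0L, fs = 10)
  st <- zscore_fit(x)
  expect_equal(st$mean, 2)
  expect_equal(st$std, sqrt(2 / 3))        # population variance

  const <- eeg_trialset(array(5, c(1, 1, 4)), 0L, fs = 10)
  stc <- zscore_fit(const)
  expect_equal(stc$mean, 5)
  expect_equal(stc$std, 0)

  # pooling is invariant under trial duplication
  one <- tiny_trialset(n_per_class = 1, seed = 3)
  two <- eeg_trialset(one$signals[c(1, 1, 2, 2), , ],
                      one$labels[c(1, 1, 2, 2)], one$fs)
  expect_equal(zscore_fit(one)$mean, zscore_fit(two)$mean)
  expect_equal(zscore_fit(one)$std, zscore_fit(two)$std)
})

test_that("z-score normalization standardizes each channel", {
  x <- eeg_trialset(array(c(1, 2, 3), c(1, 1, 3)), 0L, fs = 10)
  z <- zscore_apply(x, zscore_fit(x, epsilon = 0))
  expect_equal(as.vector(z$signals), c(-sqrt(1.5), 0, sqrt(1.5)))

  # identity when data are already standardized
  st <- structure(list(mean = 0, std = 1, epsilon = 0),
                  class = "zscore_stats")
  expect_equal(zscore_apply(z, st)$signals, z$signals)

  # zero-variance channel maps to zeros, no division blow-up
  const <- eeg_trialset(array(5, c(2, 1, 4)), c(0L, 0L), fs = 10)
  zc <- zscore_apply(const, zscore_fit(const))
  expect_true(all(zc$signals == 0))

  # fitting-set post-condition: per-channel mean 0, sd 1
  big <- tiny_trialset(n_per_class = 5, C = 3, T_len = 100, seed = 9)
  zb <- zscore_apply(big, zscore_fit(big))
  m <- matrix(aperm(zb$signals, c(2, 1, 3)), nrow = 3)
  expect_lt(max(abs(rowMeans(m))), 1e-6)
  expect_lt(max(abs(sqrt(rowMeans(m^2) - rowMeans(m)^2) - 1)), 1e-6)

  # normalization is affine and order-preserving per channel
  expect_identical(order(big$signals[1, 2, ]), order(zb$signals[1, 2, ]))

  expect_error(zscore_apply(big, zscore_fit(tiny_trialset(C = 5))),
               "channels")
})

test_that("fixture save/load round-trips bit-exactly and validates fields", {
  x <- tiny_trialset(seed = 4)
  path <- tempfile(fileext = ".rds")
  save_fixture(x, path)
  y <- load_fixture(path)
  expect_identical(y$signals, x$signals)
  expect_identical(y$labels, x$labels)
  expect_identical(y$fs, x$fs)
  expect_identical(y$channel_names, x$channel_names)

  # truncated container
  raw <- readBin(path, "raw", file.info(path)$size)
  trunc_path <- tempfile(fileext = ".rds")
  writeBin(raw[1:20], trunc_path)
  expect_error(load_fixture(trunc_path), "parse error")

  # missing field is named
  bad <- unclass(x); bad$labels <- NULL
  bad_path <- tempfile(fileext = ".rds")
  saveRDS(bad, bad_path)
  expect_error(load_fixture(bad_path), "missing field 'labels'")

  # empty-trial container
  empty <- unclass(x); empty$signals <- array(0, c(0, 4, 64))
  empty$labels <- integer(0)
  saveRDS(empty, bad_path)
  expect_error(load_fixture(bad_path), "empty")
})

test_that("EDF recordings are read back and epoched at 0-based onsets", {
  set.seed(5)
  fs <- 250
  cont <- matrix(rnorm(3 * 1000, sd = 20), 3, 1000)
  path <- tempfile(fileext = ".edf")
  write_edf(cont, fs, path, channel_names = c("Cz", "C3", "C4"))
  rec <- read_edf(path)
  expect_equal(rec$fs, fs)
  expect_equal(rec$channel_names, c("Cz", "C3", "C4"))
  # 16-bit quantization over the physical range
  expect_lt(max(abs(rec$data[, 1:1000] - cont)),
            diff(range(cont)) / 65535 + 1e-9)

  ts <- load_recording(path, "EDF", onsets = c(0, 500), window = 400,
                       labels = c(0, 1))
  expect_identical(dim(ts), c(2L, 3L, 400L))
  expect_equal(ts$signals[2, 1, 1], rec$data[1, 501])  # half-open window

  expect_error(load_recording(path, "EDF", onsets = 700, window = 400),
               "bounds")
  expect_error(load_recording(path, "GDF", onsets = 0, window = 10),
               "unsupported")
  # 1125 samples at 250 Hz are 4.5 s trials
  expect_equal(1125 / fs, 4.5)
})
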