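# Circulant count matrix: row i holds v shifted by i, so every row and
# column sums to sum(v) — balanced classes with uniform marginals.
circulant_cm <- function(v) {
  n <- length(v)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) m[i, ] <- v[((seq_len(n) - i) %% n) + 1]
  class(m) <- c("confusion_matrix", class(m))
  m
}

test_that("confusion counts match a brute-force tally", {
  set.seed(9)
  true <- sample(0:3, 100, replace = TRUE)
  pred <- sample(0:3, 100, replace = TRUE)
  cm <- confusion_matrix(true, pred, 4)
  for (i in 0:3) for (j in 0:3)
    expect_identical(cm[i + 1, j + 1], sum(true == i & pred == j))
  expect_identical(sum(cm), 100L)

  expect_identical(unname(diag(confusion_matrix(0:2, 0:2, 3))), rep(1L, 3))
  one_col <- confusion_matrix(c(0, 1, 2), c(0, 0, 0), 3)
  expect_true(all(one_col[, 2:3] == 0))
  expect_error(confusion_matrix(0:2, 0:1, 3), "differ")
  expect_error(confusion_matrix(0:3, 0:3, 3), "n_classes")
})

test_that("accuracy exposes pooled and per-class (macro) forms", {
  expect_equal(accuracy(diag(5L)), 1)
  # one error among the 72 left-hand trials prints as 98.6% at 1 d.p.
  true <- rep(0:3, each = 72)
  pred <- true
  pred[1] <- 1L
  cm <- confusion_matrix(true, pred, 4)
  expect_equal(round(100 * per_class_accuracy(cm)[1], 1), 98.6,
               ignore_attr = TRUE)
  expect_error(per_class_accuracy(confusion_matrix(c(0, 0), c(0, 1), 2)),
               "no trials")
  cm2 <- circulant_cm(c(8515, 495, 495, 495))
  expect_equal(accuracy(cm2), 0.8515)
  expect_equal(accuracy(cm2, "macro"), 0.8515)       # balanced: macro = micro
  expect_equal(unname(per_class_accuracy(cm2)), rep(0.8515, 4))
})

test_that("kappa reproduces the paired accuracy/kappa values", {
  expect_equal(cohen_kappa(diag(10L)), 1)
  # 4-class, accuracy 0.8515, uniform marginals -> 0.80 at 2 d.p.
  expect_equal(round(cohen_kappa(circulant_cm(c(8515, 495, 495, 495))), 2),
               0.80)
  # 2-class, accuracy 0.9005 -> 0.80 at 2 d.p.
  expect_equal(round(cohen_kappa(circulant_cm(c(9005, 995))), 2), 0.80)
  # chance-level uniform matrix has kappa 0
  expect_equal(cohen_kappa(matrix(5L, 4, 4)), 0, tolerance = 1e-12)
  # degenerate marginals
  m <- matrix(0L, 2, 2); m[1, 1] <- 10L
  expect_error(cohen_kappa(m), "undefined")
})

test_that("kappa equals an independent Pa/Pe computation", {
  set.seed(4)
  for (i in 1:10) {
    cm <- matrix(sample(0:20, 9, replace = TRUE), 3, 3)
    if (sum(cm) == 0) next
    tot <- sum(cm)
    pa <- sum(diag(cm)) / tot
    pe <- sum(sapply(1:3, function(k) sum(cm[k, ]) * sum(cm[, k]))) / tot^2
    if (abs(1 - pe) < 1e-12) next
    expect_equal(cohen_kappa(cm), (pa - pe) / (1 - pe), tolerance = 1e-12)
  }
})

test_that("accuracy and kappa are invariant under class relabeling", {
  set.seed(5)
  cm <- matrix(sample(1:30, 16, replace = TRUE), 4, 4)
  perm <- sample(4)
  cmp <- cm[perm, perm]
  expect_equal(accuracy(cmp), accuracy(cm))
  expect_equal(accuracy(cmp, "macro"), accuracy(cm, "macro"))
  expect_equal(cohen_kappa(cmp), cohen_kappa(cm))
})

test_that("model evaluation reports are deterministic and exportable", {
  x <- tiny_trialset(n_per_class = 4, C = 3, T_len = 64, N = 2, seed = 10)
  m <- build_ciacnet(tiny_config(), seed = 2)
  r1 <- evaluate_model(m, x)
  r2 <- evaluate_model(m, x)
  expect_identical(r1$confusion, r2$confusion)
  expect_equal(r1$accuracy, r2$accuracy)
  # balanced set: per-class accuracies average to the overall accuracy
  expect_equal(mean(r1$per_class), r1$accuracy)

  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_report(r1, jp, cp, seed = 1)
  obj <- jsonlite::read_json(jp)
  expect_equal(obj$accuracy, r1$accuracy)
  expect_equal(obj$kappa, r1$kappa)
  expect_identical(nrow(read.csv(cp)), 2L)
})
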