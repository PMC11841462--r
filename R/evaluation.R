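#' Confusion matrix of 0-based labels
#'
#' @param true,predicted integer vectors of 0-based class labels in
#'   `[0, n_classes)`.
#' @param n_classes number of classes `N`.
#' @return An `N x N` integer matrix of class `confusion_matrix`; rows are
#'   true classes, columns predicted classes.
#' @export
confusion_matrix <- function(true, predicted, n_classes) {
  ck(length(true) == length(predicted),
     "true (", length(true), ") and predicted (", length(predicted),
     ") label counts differ")
  true <- as.integer(true); predicted <- as.integer(predicted)
  n_classes <- as.integer(n_classes)
  ck(all(true >= 0L & true < n_classes) &&
       all(predicted >= 0L & predicted < n_classes),
     "labels must lie in [0, n_classes)")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1),
                               predicted = 0:(n_classes - 1)))
  for (i in seq_along(true))
    cm[true[i] + 1L, predicted[i] + 1L] <- cm[true[i] + 1L, predicted[i] + 1L] + 1L
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

as_cm <- function(cm) {
  ck(is.matrix(cm) && nrow(cm) == ncol(cm) && all(cm >= 0),
     "cm must be a square non-negative count matrix")
  ck(sum(cm) >= 1, "empty confusion matrix")
  unclass(cm)
}

#' Classification accuracy from a confusion matrix
#'
#' `type = "micro"` is pooled accuracy, `sum(diag) / sum(cm)`;
#' `type = "macro"` is the mean of the per-class accuracies
#' `TP_i / I_i` (with `I_i` the true count of class `i`). The two coincide
#' whenever the classes are balanced.
#'
#' @param cm a square count matrix (rows true, columns predicted).
#' @param type `"micro"` (pooled) or `"macro"` (mean per-class).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm, type = c("micro", "macro")) {
  cm <- as_cm(cm)
  switch(match.arg(type),
         micro = sum(diag(cm)) / sum(cm),
         macro = mean(per_class_accuracy(cm)))
}

#' @rdname accuracy
#' @export
per_class_accuracy <- function(cm) {
  cm <- as_cm(cm)
  ri <- rowSums(cm)
  ck(all(ri >= 1), "per-class accuracy undefined: some class has no trials")
  diag(cm) / ri
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(Pa - Pe) / (1 - Pe)` with `Pa` the observed
#' agreement (pooled accuracy) and `Pe = sum_i row_i * col_i / total^2` the
#' agreement expected from the marginals. For balanced uniform marginals
#' this reduces to `(acc - 1/N) / (1 - 1/N)`.
#'
#' @param cm a square count matrix (rows true, columns predicted).
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  cm <- as_cm(cm)
  tot <- sum(cm)
  pa <- sum(diag(cm)) / tot
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  if (abs(1 - pe) < 1e-15)
    stop("kappa undefined: expected agreement Pe = 1 (degenerate marginals)",
         call. = FALSE)
  (pa - pe) / (1 - pe)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted)\n")
  print(unclass(x))
  cat(sprintf("accuracy %.4f | kappa %.4f\n", accuracy(x),
              tryCatch(cohen_kappa(x), error = function(e) NA)))
  invisible(x)
}

#' Evaluate a fitted model on a test set
#'
#' Deterministic under expectation-mode attention: repeated calls produce
#' identical reports.
#'
#' @param fit a `ciacnet_fit` or `ciacnet` model.
#' @param test an [eeg_trialset()].
#' @return An `eval_report`: list with `accuracy` (micro), `macro_accuracy`,
#'   `kappa`, `per_class` accuracy vector, `per_class_counts`, `n_trials`
#'   and the `confusion` matrix.
#' @export
evaluate_model <- function(fit, test) {
  ck(inherits(fit, c("ciacnet_fit", "ciacnet")),
     "fit must be a ciacnet or ciacnet_fit")
  ck(inherits(test, "eeg_trialset"), "test must be an eeg_trialset")
  pred <- predict(fit, test, type = "class")
  n_cls <- if (inherits(fit, "ciacnet_fit")) fit$model$config$n_classes else
    fit$config$n_classes
  cm <- confusion_matrix(test$labels, pred, n_cls)
  structure(list(accuracy = accuracy(cm), macro_accuracy = accuracy(cm, "macro"),
                 kappa = cohen_kappa(cm), per_class = per_class_accuracy(cm),
                 per_class_counts = rowSums(cm), n_trials = sum(cm),
                 confusion = cm),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%% | kappa %.2f | %d trials\n",
              100 * x$accuracy, x$kappa, x$n_trials))
  cat("per-class accuracy (%):",
      paste(sprintf("%.1f", 100 * x$per_class), collapse = " "), "\n")
  invisible(x)
}

#' Write an evaluation report to JSON and the confusion matrix to CSV
#'
#' @param report an `eval_report` from [evaluate_model()].
#' @param json_path output JSON path (report fields, raw doubles).
#' @param csv_path optional CSV path for the confusion matrix (header row of
#'   class names).
#' @param seed optional seed recorded in the report.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, csv_path = NULL, seed = NULL) {
  ck(inherits(report, "eval_report"), "report must be an eval_report")
  obj <- list(accuracy = report$accuracy, kappa = report$kappa,
              per_class = as.numeric(report$per_class),
              n_trials = as.integer(report$n_trials), seed = seed)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    m <- as.data.frame(unclass(report$confusion))
    write.csv(m, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
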