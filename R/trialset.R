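#' Labeled multichannel EEG trial set
#'
#' Container for a set of motor-imagery EEG trials: a `trials x channels x
#' samples` signal array (microvolts), one integer class label per trial
#' (0-based, in `0 .. n_classes - 1`), the sampling rate and channel names.
#'
#' @param signals numeric array of dimension `trials x channels x samples`;
#'   all values must be finite.
#' @param labels integer vector of per-trial class indices in
#'   `[0, n_classes)`; length must equal the number of trials.
#' @param fs sampling rate in Hz.
#' @param channel_names optional character vector of channel labels; defaults
#'   to `"C1" ... "C<channels>"`.
#' @param n_classes number of classes; defaults to `max(labels) + 1`.
#'
#' @return An object of class `eeg_trialset` with elements `signals`,
#'   `labels`, `fs`, `channel_names`, `n_classes`.
#' @examples
#' x <- eeg_trialset(array(rnorm(2 * 3 * 10), c(2, 3, 10)), c(0L, 1L), fs = 250)
#' x
#' @export
eeg_trialset <- function(signals, labels, fs, channel_names = NULL,
                         n_classes = NULL) {
  ck(is.array(signals) && length(dim(signals)) == 3,
     "signals must be a trials x channels x samples array")
  ck(dim(signals)[1] >= 1, "trial set is empty (0 trials)")
  ck(all(is.finite(signals)), "signals contain non-finite values")
  labels <- as.integer(labels)
  ck(length(labels) == dim(signals)[1],
     "labels length (", length(labels), ") != number of trials (",
     dim(signals)[1], ")")
  ck(!anyNA(labels) && all(labels >= 0L), "labels must be integers >= 0")
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  n_classes <- as.integer(n_classes)
  ck(all(labels < n_classes), "labels must be < n_classes")
  ck(is.numeric(fs) && length(fs) == 1 && fs > 0, "fs must be a positive scalar")
  if (is.null(channel_names))
    channel_names <- paste0("C", seq_len(dim(signals)[2]))
  ck(length(channel_names) == dim(signals)[2],
     "channel_names length != number of channels")
  structure(list(signals = signals, labels = labels, fs = as.numeric(fs),
                 channel_names = as.character(channel_names),
                 n_classes = n_classes),
            class = "eeg_trialset")
}

#' @export
print.eeg_trialset <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("<eeg_trialset> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  classes:", x$n_classes, " label counts:",
      paste(tabulate(x$labels + 1L, x$n_classes), collapse = "/"), "\n")
  invisible(x)
}

#' @export
dim.eeg_trialset <- function(x) dim(x$signals)

n_trials <- function(x) dim(x$signals)[1]

subset_trials <- function(x, idx) {
  eeg_trialset(x$signals[idx, , , drop = FALSE], x$labels[idx], x$fs,
               x$channel_names, x$n_classes)
}

#' Fit per-channel Z-score normalization statistics
#'
#' Computes the per-channel mean and standard deviation of a training trial
#' set, pooled over all trials and all time points. The variance is the
#' population variance (denominator `n`). Statistics fit on the training set
#' are later applied to both training and evaluation data so that no
#' information leaks from the evaluation set.
#'
#' @param train an [eeg_trialset()] with at least one trial.
#' @param epsilon non-negative guard added to the standard deviation before
#'   dividing, so zero-variance channels map to zero instead of `Inf`.
#' @return An object of class `zscore_stats`: list with per-channel `mean`,
#'   `std` and the `epsilon` used.
#' @seealso [zscore_apply()]
#' @export
zscore_fit <- function(train, epsilon = 1e-8) {
  ck(inherits(train, "eeg_trialset"), "train must be an eeg_trialset")
  ck(epsilon >= 0, "epsilon must be >= 0")
  d <- dim(train$signals)
  # channel-major matrix: rows = channels, cols = trial x time points
  m <- matrix(aperm(train$signals, c(2, 1, 3)), nrow = d[2])
  mu <- rowMeans(m)
  v <- rowMeans(m * m) - mu^2          # population variance
  v[v < 0] <- 0                        # guard against rounding
  structure(list(mean = mu, std = sqrt(v), epsilon = epsilon),
            class = "zscore_stats")
}

#' Apply Z-score normalization
#'
#' Standardizes every channel as `(x - mean) / (std + epsilon)` with the
#' statistics from [zscore_fit()]. When the statistics were fit on the same
#' data, every non-degenerate channel of the result has mean 0 and standard
#' deviation 1; zero-variance channels map to all zeros.
#'
#' @param data an [eeg_trialset()].
#' @param stats a `zscore_stats` object with one (mean, std) pair per channel.
#' @return A normalized [eeg_trialset()] of the same shape.
#' @export
zscore_apply <- function(data, stats) {
  ck(inherits(data, "eeg_trialset"), "data must be an eeg_trialset")
  ck(inherits(stats, "zscore_stats"), "stats must come from zscore_fit()")
  d <- dim(data$signals)
  ck(length(stats$mean) == d[2],
     "stats were fit on ", length(stats$mean), " channels, data has ", d[2])
  ctr <- sweep(data$signals, 2, stats$mean, "-")
  out <- sweep(ctr, 2, stats$std + stats$epsilon, "/")
  eeg_trialset(out, data$labels, data$fs, data$channel_names, data$n_classes)
}

#' Save / load an EEG trial-set fixture
#'
#' Serializes an [eeg_trialset()] to a single-file container and reads it
#' back with field-level validation; the round trip preserves signals and
#' labels bit-exactly. The container is an RDS file holding the named fields
#' `signals`, `labels`, `fs`, `channel_names`, `n_classes`.
#'
#' @param data an [eeg_trialset()].
#' @param path file path to write to / read from.
#' @return `save_fixture` returns `path` invisibly; `load_fixture` returns
#'   the restored [eeg_trialset()].
#' @export
save_fixture <- function(data, path) {
  ck(inherits(data, "eeg_trialset"), "data must be an eeg_trialset")
  saveRDS(unclass(data), path)
  invisible(path)
}

#' @rdname save_fixture
#' @export
load_fixture <- function(path) {
  ck(file.exists(path), "fixture file not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("fixture parse error in '", path, "': ", conditionMessage(e),
         call. = FALSE))
  ck(is.list(obj), "fixture parse error: container is not a field list")
  for (f in c("signals", "labels", "fs", "channel_names", "n_classes"))
    ck(f %in% names(obj), "fixture parse error: missing field '", f, "'")
  eeg_trialset(obj$signals, obj$labels, obj$fs, obj$channel_names,
               obj$n_classes)
}
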