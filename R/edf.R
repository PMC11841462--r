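# Minimal EDF (European Data Format) adapter. EDF stores a fixed-layout
# ASCII header followed by little-endian int16 data records; this reader
# supports the subset needed to epoch continuous multichannel recordings
# into fixed-length trials. No filtering, re-referencing or artifact
# rejection is performed on load.

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

#' Write a continuous recording to an EDF file
#'
#' Fixture writer used for round-trip tests of the EDF adapter. Signals are
#' quantized to 16-bit integers over the per-channel physical range, the
#' quantization EDF itself imposes.
#'
#' @param signals numeric matrix `channels x samples` (microvolts).
#' @param fs sampling rate in Hz (must be a positive integer; one data
#'   record per second is written).
#' @param path output file path.
#' @param channel_names optional channel labels.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, channel_names = NULL) {
  ck(is.matrix(signals), "signals must be a channels x samples matrix")
  fs <- as.integer(fs)
  ck(fs >= 1, "fs must be a positive integer")
  nc <- nrow(signals); ns <- ncol(signals)
  if (is.null(channel_names)) channel_names <- paste0("C", seq_len(nc))
  n_rec <- ceiling(ns / fs)
  padded <- matrix(0, nc, n_rec * fs)
  padded[, seq_len(ns)] <- signals
  pmin <- apply(padded, 1, min); pmax <- apply(padded, 1, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("synthetic recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (nc + 1), 8); wr("", 44); wr(n_rec, 8); wr(1, 8); wr(nc, 4)
  for (s in channel_names) wr(s, 16)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr("uV", 8)
  for (i in seq_len(nc)) wr(format(pmin[i], digits = 6), 8)
  for (i in seq_len(nc)) wr(format(pmax[i], digits = 6), 8)
  for (i in seq_len(nc)) wr(dmin, 8)
  for (i in seq_len(nc)) wr(dmax, 8)
  for (i in seq_len(nc)) wr("", 80)
  for (i in seq_len(nc)) wr(fs, 8)
  for (i in seq_len(nc)) wr("", 32)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(nc)) {
      dig <- round((padded[i, cols] - pmin[i]) * scale[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path path to an EDF file.
#' @return A list with `data` (channels x samples matrix, physical units),
#'   `fs` (Hz) and `channel_names`.
#' @export
read_edf <- function(path) {
  ck(file.exists(path), "recording not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readBin(con, "raw", w)
    ck(length(raw) == w, "EDF parse error: truncated header in '", path, "'")
    trimws(rawToChar(raw))
  }
  rd(8)                              # version
  rd(80); rd(80); rd(8); rd(8)       # patient/recording/date/time
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  ck(!is.na(nc) && nc >= 1, "EDF parse error: bad signal count")
  names <- vapply(seq_len(nc), function(i) rd(16), "")
  for (i in seq_len(nc)) rd(80)
  for (i in seq_len(nc)) rd(8)
  pmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nc)) rd(80)
  spr <- vapply(seq_len(nc), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nc)) rd(32)
  ck(length(unique(spr)) == 1,
     "EDF adapter supports a single sampling rate across signals")
  fs <- spr[1] / rec_dur
  ck(is.finite(fs) && fs > 0, "EDF parse error: file declares no sampling rate")
  out <- matrix(0, nc, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nc)) {
      dig <- readBin(con, "integer", spr[i], size = 2, endian = "little")
      ck(length(dig) == spr[i], "EDF parse error: truncated record ", r)
      out[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
    }
  }
  list(data = out, fs = fs, channel_names = names)
}

#' Epoch a continuous recording into an EEG trial set
#'
#' Cuts a continuous multichannel recording into fixed-length trials at the
#' given onsets. Onsets are 0-based sample indices; each trial is the
#' half-open window `[onset, onset + window)`. The raw signal is used as-is
#' (no filtering, no artifact removal).
#'
#' @param path path to the recording file.
#' @param format recording container format; `"EDF"` is supported, `"GDF"`
#'   raises an unsupported-format error.
#' @param onsets integer vector of 0-based trial onset samples.
#' @param window trial length in samples.
#' @param labels optional 0-based class label per onset (default all 0).
#' @param n_classes optional class count.
#' @return An [eeg_trialset()] with one trial per onset.
#' @export
load_recording <- function(path, format = c("EDF", "GDF"), onsets, window,
                           labels = NULL, n_classes = NULL) {
  format <- toupper(format[1])
  if (format != "EDF")
    stop("unsupported recording format: '", format,
         "' (only EDF is supported)", call. = FALSE)
  rec <- read_edf(path)
  onsets <- as.integer(onsets)
  window <- as.integer(window)
  ck(window >= 1, "window must be >= 1 sample")
  total <- ncol(rec$data)
  bad <- onsets < 0L | onsets + window > total
  if (any(bad))
    stop("onset window [", onsets[which(bad)[1]], ", ",
         onsets[which(bad)[1]] + window, ") exceeds recording bounds (",
         total, " samples)", call. = FALSE)
  sig <- array(0, c(length(onsets), nrow(rec$data), window))
  for (i in seq_along(onsets))
    sig[i, , ] <- rec$data[, (onsets[i] + 1):(onsets[i] + window)]
  if (is.null(labels)) labels <- rep(0L, length(onsets))
  eeg_trialset(sig, labels, rec$fs, rec$channel_names, n_classes)
}
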