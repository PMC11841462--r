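#' Configuration for the synthetic motor-imagery EEG generator
#'
#' The generator emulates the spatio-spectral signature that motor imagery
#' leaves in EEG: event-related desynchronization (ERD), i.e. a
#' class-dependent attenuation of sensorimotor-rhythm band power over a
#' class-specific subset of channels, on top of broadband noise. Defaults
#' mirror a small four-class benchmark geometry: 22 channels, 1125 samples
#' (4.5 s) at 250 Hz, mu-band rhythm (8-13 Hz).
#'
#' @param n_trials_per_class trials generated per class.
#' @param n_channels number of EEG channels `C`.
#' @param n_samples samples per trial `T`.
#' @param fs sampling rate (Hz).
#' @param n_classes number of classes `N`.
#' @param rhythm_band `(low, high)` rhythm frequency band in Hz, inside
#'   `(0, fs/2)`.
#' @param erd_depth fractional amplitude attenuation in `[0, 1)` applied to
#'   the rhythm on the target channels of a trial's own class. Band power on
#'   those channels is `(1 - erd_depth)^2` times the unmodulated power.
#' @param rhythm_amplitude RMS amplitude of the unmodulated rhythm
#'   (microvolts).
#' @param noise_sd standard deviation of the additive broadband Gaussian
#'   noise (microvolts).
#' @param artifact_rate expected number of high-amplitude transient
#'   artifacts per trial (Poisson); 0 disables them.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_trials_per_class = 40, n_channels = 22,
                         n_samples = 1125, fs = 250, n_classes = 4,
                         rhythm_band = c(8, 13), erd_depth = 0.7,
                         rhythm_amplitude = 10, noise_sd = 5,
                         artifact_rate = 0, seed = 1) {
  ck(n_trials_per_class >= 1, "invalid n_trials_per_class: must be >= 1")
  ck(n_channels >= 1, "invalid n_channels: must be >= 1")
  ck(n_samples >= 8, "invalid n_samples: must be >= 8")
  ck(fs > 0, "invalid fs: must be > 0")
  ck(n_classes >= 2, "invalid n_classes: must be >= 2")
  ck(n_channels >= n_classes,
     "invalid n_channels: need at least one channel per class")
  ck(length(rhythm_band) == 2 && rhythm_band[1] > 0 &&
       rhythm_band[2] > rhythm_band[1] && rhythm_band[2] < fs / 2,
     "invalid rhythm_band: must satisfy 0 < low < high < fs/2")
  ck(erd_depth >= 0 && erd_depth < 1, "invalid erd_depth: must be in [0, 1)")
  ck(rhythm_amplitude > 0, "invalid rhythm_amplitude: must be > 0")
  ck(noise_sd >= 0, "invalid noise_sd: must be >= 0")
  ck(artifact_rate >= 0, "invalid artifact_rate: must be >= 0")
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples), fs = fs,
                 n_classes = as.integer(n_classes),
                 rhythm_band = as.numeric(rhythm_band),
                 erd_depth = erd_depth, rhythm_amplitude = rhythm_amplitude,
                 noise_sd = noise_sd, artifact_rate = artifact_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Channels whose rhythm a class attenuates
#'
#' Class-to-channel assignment is a deterministic round-robin: class `c`
#' (0-based) modulates channels `c + 1, c + 1 + N, c + 1 + 2N, ...`
#' (1-based indices), so tests can address the modulated channels
#' programmatically.
#'
#' @param class_id 0-based class index.
#' @param n_channels channel count.
#' @param n_classes class count.
#' @return Integer vector of 1-based channel indices.
#' @export
mi_target_channels <- function(class_id, n_channels, n_classes) {
  seq.int(class_id + 1L, n_channels, by = n_classes)
}

#' Generate a synthetic motor-imagery EEG trial set
#'
#' Every channel carries a band-limited oscillation (a sum of eight
#' sinusoids at frequencies drawn uniformly from `rhythm_band` with random
#' phases, amplitude-modulated by a smooth within-trial envelope and
#' normalized to RMS `rhythm_amplitude`). On the target channels of a
#' trial's own class the oscillation amplitude is scaled by
#' `1 - erd_depth` (ERD). Independent Gaussian broadband noise is added
#' everywhere, plus optional exponentially decaying high-amplitude bursts
#' mimicking transient artifacts.
#'
#' @param config a [synth_config()].
#' @return An [eeg_trialset()] with balanced, interleaved class labels.
#' @examples
#' x <- generate_mi(synth_config(n_trials_per_class = 2, n_channels = 4,
#'                               n_samples = 250, seed = 7))
#' dim(x)
#' @export
generate_mi <- function(config) {
  ck(inherits(config, "synth_config"), "config must come from synth_config()")
  set.seed(config$seed)
  C <- config$n_channels; Tn <- config$n_samples; N <- config$n_classes
  n_tot <- config$n_trials_per_class * N
  labels <- rep(seq_len(N) - 1L, config$n_trials_per_class)
  tt <- seq_len(Tn) - 1L
  env <- 0.8 + 0.2 * sin(pi * tt / (Tn - 1))   # smooth within-trial envelope
  sig <- array(0, c(n_tot, C, Tn))
  n_sin <- 8L
  for (i in seq_len(n_tot)) {
    targets <- mi_target_channels(labels[i], C, N)
    amp <- rep(config$rhythm_amplitude, C)
    amp[targets] <- amp[targets] * (1 - config$erd_depth)
    for (h in seq_len(C)) {
      f <- runif(n_sin, config$rhythm_band[1], config$rhythm_band[2])
      ph <- runif(n_sin, 0, 2 * pi)
      osc <- colSums(sin(outer(f, tt / config$fs, function(fr, s)
        2 * pi * fr * s) + ph))
      w <- env * osc
      w <- w / sqrt(mean(w^2))                 # unit RMS incl. envelope
      sig[i, h, ] <- amp[h] * w
    }
    if (config$noise_sd > 0)
      sig[i, , ] <- sig[i, , ] + matrix(rnorm(C * Tn, 0, config$noise_sd),
                                        C, Tn)
    if (config$artifact_rate > 0) {
      n_art <- stats::rpois(1, config$artifact_rate)
      tau <- 0.05 * config$fs
      for (a in seq_len(n_art)) {
        h <- sample.int(C, 1)
        t0 <- sample.int(Tn, 1)
        a_amp <- sample(c(-1, 1), 1) *
          10 * max(config$noise_sd, config$rhythm_amplitude)
        span <- t0:Tn
        sig[i, h, span] <- sig[i, h, span] +
          a_amp * exp(-(span - t0) / tau)
      }
    }
  }
  eeg_trialset(sig, labels, config$fs, n_classes = N)
}

#' Stratified train/test split of a trial set
#'
#' Splits a trial set into two disjoint sets whose union is the input,
#' stratified by class: each class contributes `round(train_fraction * n_c)`
#' trials to the first set.
#'
#' @param data an [eeg_trialset()].
#' @param train_fraction fraction in `(0, 1)` assigned to the first set.
#' @param seed RNG seed for the assignment.
#' @return A list with elements `train` and `test`, both [eeg_trialset()]s.
#' @export
split_trialset <- function(data, train_fraction, seed = 1) {
  ck(inherits(data, "eeg_trialset"), "data must be an eeg_trialset")
  ck(train_fraction > 0 && train_fraction < 1,
     "train_fraction must be in (0, 1)")
  set.seed(seed)
  tr_idx <- integer(0)
  for (c in seq_len(data$n_classes) - 1L) {
    idx <- which(data$labels == c)
    n_tr <- round(train_fraction * length(idx))
    if (n_tr < 1 || n_tr >= length(idx))
      stop("invalid split: class ", c, " would be empty in one part",
           call. = FALSE)
    tr_idx <- c(tr_idx, sample(idx, n_tr))
  }
  tr_idx <- sort(tr_idx)
  list(train = subset_trials(data, tr_idx),
       test = subset_trials(data, setdiff(seq_len(n_trials(data)), tr_idx)))
}
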