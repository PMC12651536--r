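#' Schematic 10-20 montage for the 21-electrode cap
#'
#' Channel names with schematic 2-D head coordinates (unit head radius,
#' nose up).  The coordinates only serve to define inter-electrode distances
#' for the spatial spread of the simulated evoked response; they are not
#' digitised positions.
#'
#' @return A tibble with columns `channel`, `x`, `y`.
#' @export
montage_1020 <- function() {
  tibble::tribble(
    ~channel,     ~x,    ~y,
    "Fp1",     -0.26,  0.76,
    "Fp2",      0.26,  0.76,
    "F7",      -0.65,  0.47,
    "F3",      -0.32,  0.35,
    "Fz",       0.00,  0.40,
    "F4",       0.32,  0.35,
    "F8",       0.65,  0.47,
    "A1",      -1.00, -0.10,
    "T3",      -0.80,  0.00,
    "C3",      -0.40,  0.00,
    "Cz",       0.00,  0.00,
    "C4",       0.40,  0.00,
    "T4",       0.80,  0.00,
    "A2",       1.00, -0.10,
    "T5",      -0.65, -0.47,
    "P3",      -0.32, -0.35,
    "Pz",       0.00, -0.40,
    "P4",       0.32, -0.35,
    "T6",       0.65, -0.47,
    "O1",      -0.26, -0.76,
    "O2",       0.26, -0.76)
}

#' Synthetic taste-EEG specification
#'
#' Parametric description of the simulated study: acquisition counts
#' (subjects x classes x repetitions x epochs per 15-s recording),
#' and a class-dependent evoked model superimposed on 1/f background noise.
#' Class 0 is the pure-water control and carries no evoked component; for
#' classes 1-5 the evoked oscillation grows in amplitude
#' (`gain_per_class`), spatial spread around the central/temporal foci
#' (`spread_radius`), and onset speed (`onset_latency_s` decreasing).
#'
#' @param n_subjects,n_classes,n_repetitions,epochs_per_recording Protocol
#'   counts; the defaults give the 20 x 6 x 6 x 15 = 10,800 sample design.
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording duration in seconds (15-s holds).
#' @param gain_per_class Evoked amplitude multipliers (a.u.), `[0]` must be 0
#'   and the rest strictly increasing.
#' @param spread_radius Per-class spatial decay scale (unit head radius),
#'   monotone increasing.
#' @param onset_latency_s Per-class evoked onset latency (s), non-increasing.
#' @param seed_electrodes Channel names of the evoked-response foci.
#' @param noise_sd Background noise standard deviation (a.u.).
#' @param pink_exponent Spectral slope of the 1/f background.
#' @param osc_freq Evoked oscillation frequency (Hz, inside the pass band).
#' @param ramp_s Envelope ramp duration after onset (s).
#' @param subject_gain_sd Log-scale SD of the per-subject lognormal gain.
#' @param rng_seed Base seed; identical spec + seed reproduces the dataset
#'   bit for bit.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_subjects = 20L, n_classes = 6L,
                           n_repetitions = 6L, epochs_per_recording = 15L,
                           fs = 256L, duration_s = 15,
                           gain_per_class = c(0, 0.5, 1.0, 1.5, 2.0, 2.5),
                           spread_radius = c(0.5, 0.7, 0.9, 1.1, 1.3, 1.5),
                           onset_latency_s = seq(0.20, 0.05, length.out = 6),
                           seed_electrodes = c("C3", "C4", "Cz", "T3", "T4"),
                           noise_sd = 0.5, pink_exponent = 1.0,
                           osc_freq = 8, ramp_s = 0.1,
                           subject_gain_sd = 0.15, rng_seed = 1L) {
  assert_that(n_subjects >= 1 && n_classes >= 1 && n_repetitions >= 1 &&
                epochs_per_recording >= 1, "protocol counts must be >= 1")
  assert_that(length(gain_per_class) == n_classes &&
                length(spread_radius) == n_classes &&
                length(onset_latency_s) == n_classes,
              "per-class parameter vectors must have n_classes entries")
  assert_that(gain_per_class[1] == 0,
              "class 0 is the pure-water control: gain_per_class[1] must be 0")
  if (n_classes > 2) {
    assert_that(all(diff(gain_per_class[-1]) > 0),
                "gain_per_class must be strictly increasing for classes >= 1")
  }
  assert_that(all(diff(onset_latency_s) <= 0),
              "onset_latency_s must be non-increasing")
  assert_that(abs(fs * duration_s - round(fs * duration_s)) < 1e-9,
              "fs * duration must be an integer number of samples")
  assert_that(epochs_per_recording <= floor(duration_s),
              "epochs_per_recording cannot exceed the recording duration in s")
  mont <- montage_1020()
  assert_that(all(seed_electrodes %in% mont$channel),
              "seed_electrodes must be montage channel names")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_classes = as.integer(n_classes),
                 n_repetitions = as.integer(n_repetitions),
                 epochs_per_recording = as.integer(epochs_per_recording),
                 fs = as.integer(fs), duration_s = duration_s,
                 n_electrodes = nrow(mont),
                 gain_per_class = gain_per_class,
                 spread_radius = spread_radius,
                 onset_latency_s = onset_latency_s,
                 seed_electrodes = seed_electrodes,
                 noise_sd = noise_sd, pink_exponent = pink_exponent,
                 osc_freq = osc_freq, ramp_s = ramp_s,
                 subject_gain_sd = subject_gain_sd,
                 rng_seed = as.integer(rng_seed),
                 montage = mont),
            class = "synthetic_spec")
}

#' Desk-scale synthetic specification
#'
#' Same evoked/noise model as [synthetic_spec()] but with a reduced protocol
#' (4 subjects x 6 classes x 1 repetition x 15 epochs = 360 samples) so the
#' training harness runs quickly on one CPU.
#' @param ... Overrides forwarded to [synthetic_spec()].
#' @export
desk_synthetic_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 4L, n_repetitions = 1L)
  do.call(synthetic_spec, utils::modifyList(defaults, args))
}

# 1/f ("pink") noise: white Gaussian noise shaped in the frequency domain by
# |f|^(-exponent/2), DC removed, rescaled to the requested SD.  One column
# per electrode.
pink_noise_matrix <- function(n, n_cols, exponent, sd_target) {
  wh <- matrix(rnorm(n * n_cols), n, n_cols)
  if (sd_target <= 0) return(wh * 0)
  spec <- stats::mvfft(wh)
  freq <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1)))
  shape <- c(0, freq[-1]^(-exponent / 2))
  out <- Re(stats::mvfft(spec * shape, inverse = TRUE)) / n
  sds <- apply(out, 2, stats::sd)
  sweep(out, 2, sds / sd_target, "/")
}

# Per-electrode evoked weight: Gaussian decay of the distance to the nearest
# seed electrode, scale = the class spread radius.
electrode_weights <- function(spec, class) {
  mont <- spec$montage
  seeds <- mont[mont$channel %in% spec$seed_electrodes, c("x", "y")]
  d <- vapply(seq_len(nrow(mont)), function(i) {
    min(sqrt((mont$x[i] - seeds$x)^2 + (mont$y[i] - seeds$y)^2))
  }, numeric(1))
  exp(-0.5 * (d / spec$spread_radius[class + 1L])^2)
}

subject_gain <- function(spec, subject) {
  with_seed(mix_seed(spec$rng_seed, 1000L, subject),
            rlnorm(1, 0, spec$subject_gain_sd))
}

#' Simulate one 15-s taste-EEG recording
#'
#' The signal at electrode e is 1/f background noise plus, for classes >= 1,
#' `g_subject * gain[class] * w_e(class) * env(t) * sin(2 pi f t + phi)`:
#' an evoked narrow-band oscillation whose electrode weight `w_e` decays
#' with distance from the nearest seed electrode, whose envelope ramps up
#' over `ramp_s` after the class onset latency and holds, whose subject gain
#' is lognormal, and whose phase is random per recording.  Reproducible
#' given the spec seed and the (subject, class, repetition) ids.
#'
#' @param spec A [synthetic_spec()].
#' @param subject Subject id (1-based).
#' @param class Stimulus class, 0 .. n_classes-1 (0 = control).
#' @param repetition Repetition id (1-based).
#' @return A `taste_recording`: list with `signal` (electrodes x samples),
#'   ids, and `fs`.
#' @export
generate_recording <- function(spec, subject, class, repetition) {
  assert_that(inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec")
  assert_that(length(class) == 1 && class %in% (seq_len(spec$n_classes) - 1L),
              sprintf("unknown class %s", paste(class, collapse = ",")))
  n <- as.integer(spec$fs * spec$duration_s)
  g_subj <- subject_gain(spec, subject)
  sig <- with_seed(mix_seed(spec$rng_seed, subject, class, repetition), {
    noise <- t(pink_noise_matrix(n, spec$n_electrodes, spec$pink_exponent,
                                 spec$noise_sd))
    phi <- runif(1, 0, 2 * pi)
    gain <- spec$gain_per_class[class + 1L]
    if (gain > 0) {
      tt <- (seq_len(n) - 1) / spec$fs
      onset <- spec$onset_latency_s[class + 1L]
      env <- pmin(pmax((tt - onset) / spec$ramp_s, 0), 1)
      wave <- env * sin(2 * pi * spec$osc_freq * tt + phi)
      w_e <- electrode_weights(spec, class)
      noise + (g_subj * gain) * outer(w_e, wave)
    } else {
      noise
    }
  })
  rownames(sig) <- spec$montage$channel
  structure(list(signal = sig, subject = as.integer(subject),
                 class = as.integer(class),
                 repetition = as.integer(repetition), fs = spec$fs),
            class = "taste_recording")
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero phase); output length equals input length.  The default 0.5-45 Hz
#' band removes drift and high-frequency noise from the recordings before
#' segmentation.
#'
#' @param x Numeric vector, or an electrodes x samples matrix (filtered
#'   row-wise), or a `taste_recording`.
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz (taken from the recording when available).
#' @return The filtered object, same shape/class as the input.
#' @export
bandpass <- function(x, low = 0.5, high = 45, fs = NULL) {
  if (inherits(x, "taste_recording")) {
    x$signal <- bandpass(x$signal, low, high, fs %||% x$fs)
    return(x)
  }
  assert_that(!is.null(fs), "fs is required")
  assert_that(low > 0 && low < high && high < fs / 2,
              "band must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  if (is.matrix(x)) {
    t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Segment a recording into consecutive 1-s epochs
#'
#' Non-overlapping epochs of `epoch_s` seconds; a trailing remainder shorter
#' than one epoch is discarded.  A 15-s recording at 256 Hz yields 15 epochs
#' of 21 x 256.
#'
#' @param rec A `taste_recording`.
#' @param epoch_s Epoch duration in seconds.
#' @return A `taste_dataset`: list with `x` (electrodes x samples x epochs
#'   array) and `meta` (tibble: sample, label, subject, repetition, epoch).
#' @export
segment <- function(rec, epoch_s = 1.0) {
  assert_that(inherits(rec, "taste_recording"), "rec must be a taste_recording")
  len <- as.integer(rec$fs * epoch_s)
  total <- ncol(rec$signal)
  assert_that(len <= total, "epoch is longer than the recording")
  n_ep <- total %/% len
  x <- array(0, c(nrow(rec$signal), len, n_ep))
  for (i in seq_len(n_ep)) {
    x[, , i] <- rec$signal[, ((i - 1) * len + 1):(i * len)]
  }
  meta <- tibble::tibble(sample = seq_len(n_ep), label = rec$class,
                         subject = rec$subject, repetition = rec$repetition,
                         epoch = seq_len(n_ep))
  new_taste_dataset(x, meta)
}

new_taste_dataset <- function(x, meta, spec = NULL) {
  structure(list(x = x, meta = meta, spec = spec), class = "taste_dataset")
}

#' @export
print.taste_dataset <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<taste_dataset: %d epochs of %d x %d, %d class(es), %d subject(s)>\n",
              d[3], d[1], d[2], length(unique(x$meta$label)),
              length(unique(x$meta$subject))))
  invisible(x)
}

#' Number of epochs in a dataset
#' @param ds A `taste_dataset`.
#' @export
n_samples <- function(ds) dim(ds$x)[3]

#' Subset a dataset by epoch index
#' @param ds A `taste_dataset`.
#' @param idx Integer indices into the epoch axis.
#' @export
dataset_subset <- function(ds, idx) {
  meta <- ds$meta[idx, , drop = FALSE]
  meta$sample <- seq_len(nrow(meta))
  new_taste_dataset(ds$x[, , idx, drop = FALSE], meta, ds$spec)
}

#' Generate a full labelled synthetic dataset
#'
#' For every (subject, class, repetition) triple: simulate the recording,
#' band-pass filter it (0.5-45 Hz, on the continuous recording so epoch
#' edges carry no filter transients), and cut consecutive 1-s epochs.  The
#' total count is always `n_subjects * n_classes * n_repetitions *
#' epochs_per_recording` with exact class balance.
#'
#' @param spec A [synthetic_spec()].
#' @param filter_band Band edges in Hz (`NULL` to skip filtering).
#' @return A `taste_dataset` with `x` (electrodes x samples x N array) and
#'   `meta` (tibble: sample, label, subject, repetition, epoch).
#' @export
generate_dataset <- function(spec, filter_band = c(0.5, 45)) {
  assert_that(inherits(spec, "synthetic_spec"), "spec must be a synthetic_spec")
  len <- spec$fs
  n_per_rec <- spec$epochs_per_recording
  n_total <- spec$n_subjects * spec$n_classes * spec$n_repetitions * n_per_rec
  x <- array(0, c(spec$n_electrodes, len, n_total))
  meta <- vector("list", spec$n_subjects * spec$n_classes * spec$n_repetitions)
  pos <- 0L; mrow <- 0L
  for (subject in seq_len(spec$n_subjects)) {
    for (class in seq_len(spec$n_classes) - 1L) {
      for (rep in seq_len(spec$n_repetitions)) {
        rec <- generate_recording(spec, subject, class, rep)
        if (!is.null(filter_band)) {
          rec <- bandpass(rec, filter_band[1], filter_band[2])
        }
        seg <- segment(rec, 1.0)
        keep <- seq_len(n_per_rec)
        x[, , pos + keep] <- seg$x[, , keep]
        mrow <- mrow + 1L
        meta[[mrow]] <- tibble::tibble(label = class, subject = subject,
                                       repetition = rep, epoch = keep)
        pos <- pos + n_per_rec
      }
    }
  }
  meta <- dplyr::bind_rows(meta)
  meta <- tibble::tibble(sample = seq_len(nrow(meta)), meta)
  new_taste_dataset(x, meta, spec)
}

#' Write / read a dataset container
#'
#' Single-file container mirroring the layout `samples` (N x E x T),
#' `labels`, `subjects`, `repetitions`, `montage`, `spec_json`.
#'
#' @param ds A `taste_dataset`.
#' @param path File path.
#' @export
write_eeg_dataset <- function(ds, path) {
  spec_json <- if (!is.null(ds$spec)) {
    as.character(jsonlite::toJSON(ds$spec[setdiff(names(ds$spec), "montage")],
                                  auto_unbox = TRUE, digits = NA))
  } else NA_character_
  saveRDS(list(samples = ds$x, labels = ds$meta$label,
               subjects = ds$meta$subject, repetitions = ds$meta$repetition,
               epochs = ds$meta$epoch,
               montage = montage_1020()$channel, spec_json = spec_json),
          path)
  invisible(path)
}

#' @rdname write_eeg_dataset
#' @export
read_eeg_dataset <- function(path) {
  obj <- readRDS(path)
  req <- c("samples", "labels", "subjects", "repetitions")
  missing <- setdiff(req, names(obj))
  assert_that(length(missing) == 0,
              sprintf("corrupt dataset container %s: missing key(s) %s",
                      path, paste(missing, collapse = ", ")))
  meta <- tibble::tibble(sample = seq_along(obj$labels), label = obj$labels,
                         subject = obj$subjects,
                         repetition = obj$repetitions,
                         epoch = obj$epochs %||% NA_integer_)
  new_taste_dataset(obj$samples, meta)
}
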