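test_that("the montage has the 21 named 10-20 channels", {
  m <- montage_1020()
  expect_identical(nrow(m), 21L)
  expect_setequal(m$channel,
                  c("Fz", "Cz", "Pz", "T3", "T4", "C3", "C4", "Fp1", "Fp2",
                    "F7", "F8", "T5", "T6", "O1", "O2", "F3", "F4", "P3",
                    "P4", "A1", "A2"))
  expect_false(anyDuplicated(m$channel) > 0)
})

test_that("synthetic_spec enforces its class-structure invariants", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_error(synthetic_spec(gain_per_class = c(0.1, 1:5)), "control")
  expect_error(synthetic_spec(gain_per_class = c(0, 2, 1, 3, 4, 5)),
               "increasing")
  expect_error(synthetic_spec(onset_latency_s = c(0.1, 0.2, rep(0.05, 4))),
               "non-increasing")
  expect_error(synthetic_spec(epochs_per_recording = 16L), "duration")
})

test_that("class 0 recordings are pure noise; evoked RMS grows with class", {
  spec <- synthetic_spec(noise_sd = 0, rng_seed = 5)
  r0 <- generate_recording(spec, 1, 0, 1)
  expect_true(all(r0$signal == 0))  # control with no noise is exactly zero
  r1 <- generate_recording(spec, 1, 1, 1)
  r5 <- generate_recording(spec, 1, 5, 1)
  rms <- function(r) sqrt(mean(r$signal^2))
  expect_gt(rms(r5), rms(r1))
  expect_true(all(is.finite(r1$signal)))
  expect_error(generate_recording(spec, 1, 9, 1), "unknown class")
  # reproducibility: identical ids give identical recordings
  expect_identical(generate_recording(synthetic_spec(rng_seed = 5), 2, 3, 1),
                   generate_recording(synthetic_spec(rng_seed = 5), 2, 3, 1))
})

test_that("background noise has a 1/f spectral slope near the requested exponent", {
  spec <- synthetic_spec(rng_seed = 7, pink_exponent = 1)
  r <- generate_recording(spec, 1, 0, 1)
  # Welch-style periodogram regression on a few electrodes
  slopes <- vapply(1:5, function(e) {
    sp <- stats::spec.pgram(stats::ts(r$signal[e, ], frequency = spec$fs),
                            spans = 15, plot = FALSE, taper = 0)
    keep <- sp$freq > 1 & sp$freq < 100
    unname(stats::coef(stats::lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2])
  }, numeric(1))
  expect_lt(abs(mean(slopes) + spec$pink_exponent), 0.3)
})

test_that("the band-pass keeps the pass band and rejects DC and 100 Hz", {
  fs <- 256
  n <- 40 * fs
  tt <- (seq_len(n) - 1) / fs
  mid <- (15 * fs):(25 * fs)  # steady-state region away from edge transients
  # DC is outside the band
  dc <- bandpass(rep(1, n), fs = fs)
  expect_lt(max(abs(dc[mid])), 0.01)
  # 10 Hz passes with ~unit gain
  s10 <- bandpass(sin(2 * pi * 10 * tt), fs = fs)
  expect_lt(abs(max(abs(s10[mid])) - 1), 0.05)
  # 100 Hz is attenuated
  s100 <- bandpass(sin(2 * pi * 100 * tt), fs = fs)
  expect_lt(max(abs(s100[mid])), 0.05)
  expect_error(bandpass(rep(0, n), low = 50, high = 40, fs = fs), "band")
  expect_error(bandpass(rep(0, n), low = 0.5, high = 200, fs = fs), "band")
})

test_that("segmentation cuts consecutive non-overlapping epochs with a floor rule", {
  spec <- synthetic_spec(rng_seed = 3)
  rec <- generate_recording(spec, 1, 2, 1)
  seg <- segment(rec)
  expect_identical(n_samples(seg), 15L)
  expect_identical(dim(seg$x)[1:2], c(21L, 256L))
  # epochs tile the recording in order
  expect_equal(seg$x[, , 2], unname(rec$signal[, 257:512]))
  expect_true(all(seg$meta$label == 2L))
  # 1-s recording -> exactly the recording back
  rec1 <- rec; rec1$signal <- rec$signal[, 1:256]
  expect_identical(n_samples(segment(rec1)), 1L)
  expect_equal(segment(rec1)$x[, , 1], unname(rec1$signal))
  # 2.5-s recording -> 2 epochs, tail discarded
  rec2 <- rec; rec2$signal <- rec$signal[, 1:640]
  expect_identical(n_samples(segment(rec2)), 2L)
  rec3 <- rec; rec3$signal <- rec$signal[, 1:100, drop = FALSE]
  expect_error(segment(rec3), "longer than")
})

test_that("dataset counts follow the four-factor product with exact balance", {
  spec <- synthetic_spec(n_subjects = 2L, n_classes = 3L, n_repetitions = 2L,
                         epochs_per_recording = 5L,
                         gain_per_class = c(0, 1, 2),
                         spread_radius = c(0.5, 0.7, 0.9),
                         onset_latency_s = c(0.2, 0.15, 0.1), rng_seed = 9)
  ds <- generate_dataset(spec)
  expect_identical(n_samples(ds), 2L * 3L * 2L * 5L)
  expect_true(all(table(ds$meta$label) == 20L))
  expect_identical(dim(ds$x)[1:2], c(21L, 256L))
  # single-cell protocol
  tiny <- tiny_synthetic_spec(epochs_per_recording = 1L, duration_s = 1)
  expect_identical(n_samples(generate_dataset(tiny)), 2L)
  # bit-identical reproduction from the same spec + seed
  ds2 <- generate_dataset(spec)
  expect_identical(ds$x, ds2$x)
  expect_identical(ds$meta, ds2$meta)
})

test_that("seed-electrode RMS increases strictly with class index", {
  # >= 100 epochs per class, default evoked/noise parameters
  spec <- synthetic_spec(n_subjects = 2L, n_repetitions = 4L, rng_seed = 13)
  ds <- generate_dataset(spec)
  sel <- which(montage_1020()$channel %in% spec$seed_electrodes)
  rms <- vapply(0:5, function(cl) {
    idx <- which(ds$meta$label == cl)
    mean(sqrt(apply(ds$x[sel, , idx, drop = FALSE]^2, 3, mean)))
  }, numeric(1))
  expect_gte(min(table(ds$meta$label)), 100L)
  expect_true(all(diff(rms) > 0))
})

test_that("dataset containers round-trip", {
  ds <- generate_dataset(tiny_synthetic_spec(rng_seed = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  write_eeg_dataset(ds, path)
  back <- read_eeg_dataset(path)
  expect_identical(back$x, ds$x)
  expect_identical(back$meta$label, ds$meta$label)
  expect_identical(back$meta$subject, ds$meta$subject)
  # corrupt container diagnostics name the missing keys
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(samples = ds$x), bad)
  expect_error(read_eeg_dataset(bad), "missing key")
})
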