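test_that("the band-pass keeps the passband and kills the stopband", {
  fs <- 250
  t <- (0:(6 * fs - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  mk <- function(f) raw_recording(matrix(sin(2 * pi * f * t), 1), "C3", fs)
  f50 <- bandpass(mk(50))
  expect_lt(rms(f50$signal) / rms(mk(50)$signal), 0.05)
  f15 <- bandpass(mk(15))
  expect_gt(rms(f15$signal) / rms(mk(15)$signal), 0.90)
  zero <- bandpass(raw_recording(matrix(0, 1, 500), "C3", fs))
  expect_identical(max(abs(zero$signal)), 0)
  expect_error(bandpass(mk(15), filter_spec(band = c(8, 130))), "Nyquist")
  expect_error(filter_spec(band = c(30, 8)), "lo < hi")
})

test_that("EOG removal drops exactly the three EOG channels", {
  sim <- small_sim(n_per_class = 2, seed = 9)
  rec <- sim$recording
  out <- remove_eog(rec)
  expect_identical(length(out$channel_names), 22L)
  expect_false(any(grepl("^EOG", out$channel_names)))
  # EEG rows are untouched bit-for-bit and keep their order
  keep <- !grepl("^EOG", rec$channel_names)
  expect_identical(out$signal, rec$signal[keep, ])
  expect_identical(out$channel_names, rec$channel_names[keep])

  no_eog <- raw_recording(matrix(0, 2, 10), c("C3", "C4"), 250)
  expect_error(remove_eog(no_eog), "EOG-left")
  expect_identical(remove_eog(no_eog, strict = FALSE), no_eog)
})

test_that("epoch extraction uses the half-open 3-6 s window", {
  fs <- 250
  n <- 4000
  ramp <- raw_recording(matrix(seq_len(n) - 1, 1, byrow = TRUE), "C3", fs,
                        events = data.frame(onset = c(0L, 1500L),
                                            code = c(769L, 770L)))
  e <- extract_epochs(ramp, c(3, 6))
  expect_identical(dim(e$data), c(2L, 1L, 750L))       # round(3 s * 250)
  # epoch k starts at onset + round(3 * fs): the ramp exposes the indices
  expect_identical(e$data[1, 1, 1], 750)
  expect_identical(e$data[2, 1, 1], 1500 + 750)
  expect_identical(e$data[2, 1, 750], 1500 + 750 + 749)
  expect_identical(e$labels, c(0L, 1L))                # from cue codes

  const <- raw_recording(matrix(1, 1, 2000), "C3", fs,
                         events = data.frame(onset = 0L, code = 769L))
  expect_true(all(extract_epochs(const, c(3, 6))$data == 1))

  short <- raw_recording(matrix(0, 1, 1550), "C3", fs,
                         events = data.frame(onset = c(0L, 100L),
                                             code = c(769L, 770L)))
  expect_error(extract_epochs(short, c(3, 6)), "trial\\(s\\) 2")
})

test_that("explicit labels and side-car label files override event codes", {
  fs <- 250
  rec <- raw_recording(matrix(0, 1, 2000), "C3", fs,
                       events = data.frame(onset = c(0L, 100L),
                                           code = c(1024L, 1024L)))
  e <- extract_epochs(rec, c(3, 6), labels = c(3L, 1L))
  expect_identical(e$labels, c(3L, 1L))
  sidecar <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2", "0"), sidecar)
  expect_identical(extract_epochs(rec, c(3, 6), labels = sidecar)$labels,
                   c(2L, 0L))
  expect_error(extract_epochs(rec, c(3, 6), labels = 0L), "labels length")
})

test_that("channel selection restricts and reorders without touching data", {
  e <- tiny_epochs(n_trials = 4, n_ch = 3, n_s = 32)
  two <- select_channels(e, c("C4", "C3"))
  expect_identical(two$channel_names, c("C4", "C3"))
  expect_identical(two$data[, 1, ], e$data[, 2, ])
  expect_identical(two$data[, 2, ], e$data[, 1, ])
  ident <- select_channels(e, e$channel_names)
  expect_identical(ident$data, e$data)
  expect_error(select_channels(e, c("C3", "F7")), "F7")
})

test_that("the full pipeline emits the model-ready layout", {
  sim <- small_sim(n_per_class = 3, seed = 10)
  e <- preprocess_pipeline(sim$recording)
  expect_identical(dim(e$data), c(12L, 22L, 240L))
  expect_identical(e$labels, sim$labels)
  expect_equal(e$fs, 80)

  # composing the stages by hand gives the identical result
  manual <- wpd_reconstruct(
    extract_epochs(remove_eog(bandpass(sim$recording)), c(3, 6)),
    wpd_config())
  expect_identical(e$data, manual$data)

  picked <- preprocess_pipeline(sim$recording, channels = c("C3", "C4"))
  expect_identical(dim(picked$data), c(12L, 2L, 240L))

  zero <- raw_recording(matrix(0, 25, 2000), iv2a_channels(), 250,
                        events = data.frame(onset = 0L, code = 769L))
  ez <- preprocess_pipeline(zero)
  expect_identical(max(abs(ez$data)), 0)

  # errors carry the failing stage's name
  expect_error(preprocess_pipeline(sim$recording,
                                   channels = c("C3", "Qz")),
               "select_channels")
})
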