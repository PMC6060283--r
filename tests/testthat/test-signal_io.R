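test_that("matrix dialect round-trips signal, header and annotations", {
  rec <- recording(matrix(sin(1:600), nrow = 3), fs = 20,
                   channel_ids = c("A", "B", "C"),
                   annotations = data.frame(onset = 2, offset = 4))
  path <- withr::local_tempfile(fileext = ".mat")
  write_recording(rec, path)
  back <- read_recording(path, "matrix",
                         annotation_path = paste0(path, ".ann"))
  expect_equal(back$signal, rec$signal, tolerance = 1e-10)
  expect_equal(back$fs, 20)
  expect_equal(back$channel_ids, c("A", "B", "C"))
  expect_equal(back$annotations$onset, 2)
  expect_equal(rec_duration(back), 10)
})

test_that("matrix reader demands a sampling rate and honours fs_hint", {
  path <- withr::local_tempfile()
  write.table(matrix(1:20, nrow = 2), path,
              row.names = FALSE, col.names = FALSE)
  expect_error(read_recording(path, "matrix"), "sampling rate")
  rec <- read_recording(path, "matrix", fs_hint = 256)
  # 6x921600-style identity at small scale: duration = n_samples / fs
  expect_equal(ncol(rec$signal), 10L)
  expect_equal(rec_duration(rec), 10 / 256)
})

test_that("EDF writer/reader round-trip preserves shape, rate and values", {
  withr::local_seed(7)
  sig <- rbind(100 * sin(2 * pi * 3 * (0:639) / 64),
               rnorm(640, sd = 40))
  rec <- recording(sig, fs = 64, channel_ids = c("F3", "F4"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path, "edf")
  expect_equal(back$fs, 64)
  expect_equal(ncol(back$signal), 10 * back$fs)   # 10 s duration identity
  expect_equal(back$channel_ids, c("F3", "F4"))
  # 16-bit quantisation: worst-case error is half a digital step
  step <- (max(sig) - min(sig)) / 65535
  expect_lt(max(abs(back$signal - rec$signal)), step)
})

test_that("annotations outside the record duration are rejected", {
  expect_error(
    recording(matrix(0, 1, 100), fs = 10,
              annotations = data.frame(onset = 11, offset = 12)),
    "outside record duration")
  expect_error(
    recording(matrix(0, 1, 100), fs = 10,
              annotations = data.frame(onset = 5, offset = 4)),
    "onset < offset")
})

test_that("notch filter attenuates the target tone and spares the passband", {
  fs <- 256
  tt <- (0:(20 * fs - 1)) / fs
  mid <- seq(fs, length(tt) - fs)    # ignore filter edge transients
  rms <- function(x) sqrt(mean(x^2))

  tone50 <- recording(matrix(sin(2 * pi * 50 * tt), 1), fs)
  out50 <- notch_filter(tone50, preprocess_config(notch_freq = 50))
  expect_lt(rms(out50$signal[1, mid]), 0.1 * rms(tone50$signal[1, mid]))

  tone10 <- recording(matrix(sin(2 * pi * 10 * tt), 1), fs)
  out10 <- notch_filter(tone10, preprocess_config(notch_freq = 50))
  expect_lt(abs(rms(out10$signal[1, mid]) / rms(tone10$signal[1, mid]) - 1),
            0.05)

  dc <- recording(matrix(1, 1, length(tt)), fs)
  outdc <- notch_filter(dc, preprocess_config(notch_freq = 50))
  expect_lt(max(abs(outdc$signal[1, mid] - 1)), 0.01)  # up to edge transient

  expect_error(notch_filter(recording(matrix(0, 1, 100), fs = 90),
                            preprocess_config(notch_freq = 50,
                                              target_fs = 256)),
               "Nyquist")
})

test_that("resampling halves 512 Hz to 256 Hz and keeps tone frequency", {
  fs <- 512
  tt <- (0:1023) / fs
  rec <- recording(matrix(sin(2 * pi * 5 * tt), 1), fs)
  down <- resample_to(rec, 256)
  expect_equal(down$fs, 256)
  expect_equal(ncol(down$signal), 512L)
  expect_equal(rec_duration(down), rec_duration(rec))

  # dominant spectral peak stays at 5 Hz
  longer <- recording(matrix(sin(2 * pi * 5 * (0:(8 * fs - 1)) / fs), 1), fs)
  spec <- stats::spec.pgram(resample_to(longer, 256)$signal[1, ],
                            plot = FALSE, taper = 0)
  peak_hz <- spec$freq[which.max(spec$spec)] * 256
  expect_equal(peak_hz, 5, tolerance = 0.2)

  expect_identical(resample_to(rec, fs)$signal, rec$signal)
})

test_that("channel selection subsets, reorders and validates ids", {
  rec <- recording(matrix(1:40, nrow = 4), fs = 10,
                   channel_ids = c("C1", "C2", "C3", "C4"))
  sel <- select_channels(rec, c("C3", "C1"))
  expect_equal(sel$channel_ids, c("C3", "C1"))
  expect_equal(unname(sel$signal[1, ]), unname(rec$signal[3, ]))
  expect_equal(sel$annotations, rec$annotations)
  ident <- select_channels(rec, rec$channel_ids)
  expect_equal(ident$signal, rec$signal)
  expect_error(select_channels(rec, c("C1", "CH999")), "CH999")
})

test_that("notch and resample approximately commute on band-limited tones", {
  fs <- 512
  tt <- (0:(10 * fs - 1)) / fs
  rec <- recording(matrix(sin(2 * pi * 10 * tt) + 0.3 * sin(2 * pi * 30 * tt),
                          1), fs)
  cfg <- preprocess_config(notch_freq = 50, target_fs = 256)
  a <- resample_to(notch_filter(rec, cfg), 256)$signal[1, ]
  b <- notch_filter(resample_to(rec, 256), cfg)$signal[1, ]
  mid <- seq(256, length(a) - 256)
  expect_gt(stats::cor(a[mid], b[mid]), 0.999)
})
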