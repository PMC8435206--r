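test_that("recording construction validates channels, lengths, and rate", {
  rec <- new_recording(cbind(rnorm(500), rnorm(500)), rnorm(500), 250)
  expect_s3_class(rec, "sleep_recording")
  expect_equal(ncol(rec$brain), 2)

  # single brain channel is the minimum valid configuration
  rec1 <- new_recording(rnorm(500), rnorm(500), 250)
  expect_equal(ncol(rec1$brain), 1)

  expect_error(new_recording(rnorm(500), rnorm(400), 250), "same number")
  expect_error(new_recording(rnorm(500), rnorm(500), 200), ">= 250")
})

test_that("binary format round-trips samples bit-exactly", {
  set.seed(31)
  rec <- new_recording(cbind(rnorm(1000), rnorm(1000)), rnorm(1000), 250,
                       start_time = 8, light_onset = 8)
  path <- file.path(tempdir(), "rt.bin")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$brain, rec$brain)
  expect_identical(back$emg, rec$emg)
  expect_equal(back$sampling_rate, 250)
  expect_equal(back$start_time, 8)
})

test_that("CSV round-trip preserves channel roles and values", {
  set.seed(32)
  rec <- new_recording(cbind(eeg1 = rnorm(500), eeg2 = rnorm(500)),
                       rnorm(500), 250, channel_names = c("eeg1", "eeg2"))
  path <- file.path(tempdir(), "rt.csv")
  write_recording(rec, path)
  back <- read_recording(path, sampling_rate = 250)
  expect_equal(back$brain, rec$brain, tolerance = 1e-12)
  expect_equal(back$emg, rec$emg, tolerance = 1e-12)

  # explicit channel_map overrides name-based role inference
  back2 <- read_recording(path, sampling_rate = 250,
                          channel_map = c(eeg1 = "brain", eeg2 = "emg",
                                          emg = "brain"))
  expect_equal(ncol(back2$brain), 2)
  expect_equal(back2$emg, rec$brain[, 2], tolerance = 1e-12)
})

test_that("EDF round-trip recovers samples up to 16-bit quantization", {
  set.seed(33)
  rec <- new_recording(cbind(100 * rnorm(750)), 50 * rnorm(750), 250)
  path <- file.path(tempdir(), "rt.edf")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(ncol(back$brain), 1)
  expect_equal(back$sampling_rate, 250)
  rng <- diff(range(rec$brain))
  expect_lt(max(abs(back$brain - rec$brain)), rng / 65535 * 1.01)
  expect_gt(cor(back$emg, rec$emg), 0.999999)
})

test_that("reading fails informatively on bad inputs", {
  expect_error(read_recording("nope.bin"), "not found")
  path <- file.path(tempdir(), "noemg.csv")
  write.csv(data.frame(a = 1:10, b = 1:10), path, row.names = FALSE)
  expect_error(read_recording(path, sampling_rate = 250), "EMG")
  path2 <- file.path(tempdir(), "norate.csv")
  write.csv(data.frame(a = 1:10, emg = 1:10), path2, row.names = FALSE)
  expect_error(read_recording(path2), "sampling_rate")
})

test_that("hypnogram TSV round-trips states and annotations", {
  h <- hypnogram(c("W", "NR", "R", "W"), certainty = c(1, .95, .5, .99),
                 uncertain = c(FALSE, FALSE, TRUE, FALSE))
  path <- file.path(tempdir(), "h.tsv")
  write_hypnogram(h, path)
  # on-disk dialect uses 0-based epoch_index
  raw <- read.delim(path)
  expect_equal(raw$epoch_index, 0:3)
  back <- read_hypnogram(path)
  expect_equal(back$state, h$state)
  expect_equal(back$epoch, h$epoch)
  expect_equal(back$certainty, h$certainty)
  expect_equal(back$uncertain, h$uncertain)
})
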