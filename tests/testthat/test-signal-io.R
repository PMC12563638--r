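test_that("read_recording parses numeric CSV with and without header", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,10", "2,20", "3,30", "4,40"), f)
  rec <- read_recording(f, fs = 128)
  expect_s3_class(rec, "recording")
  expect_equal(dim(rec$data), c(4, 2))
  expect_equal(rec$data[, 1], 1:4, ignore_attr = TRUE)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("PZ,T7", "1,10", "2,20", "3,30", "4,40"), f2)
  rec2 <- read_recording(f2, fs = 128)
  expect_equal(rec2$channels, c("PZ", "T7"))
  expect_equal(rec2$data, rec$data, ignore_attr = TRUE)
})

test_that("read_recording errors name the offending cell and mismatches", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,10", "2,20", "oops,30", "4,40"), f)
  expect_error(read_recording(f, fs = 128), "row 3")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,10", "2,20"), f2)
  expect_error(read_recording(f2, fs = 128, channels = c("a", "b", "c")),
               "2 columns but 3 channel labels")
  expect_error(read_recording(file.path(tempdir(), "no-such.csv"), 128),
               "not found")
  expect_error(read_recording("x.edf", fs = 128), "EDF")
})

test_that("write_recording / read_recording round-trips to 1e-9", {
  set.seed(41)
  rec <- recording(matrix(rnorm(200 * 3) * 50, ncol = 3), fs = 128,
                   channels = c("AF3", "PZ", "T8"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  back <- read_recording(f, fs = 128)
  expect_equal(back$channels, rec$channels)
  expect_lt(max(abs(back$data - rec$data)), 1e-9)
})

test_that("remove_dc centres every channel and is idempotent", {
  expect_equal(remove_dc(c(5, 5, 5, 5)), rep(0, 4))
  x <- sin(2 * pi * 7 * (0:255) / 128)
  expect_lt(max(abs(remove_dc(x + 3) - x)), 1e-10)

  set.seed(5)
  rec <- recording(matrix(rnorm(512 * 2, mean = 12), ncol = 2), 128,
                   c("a", "b"))
  out <- remove_dc(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
  twice <- remove_dc(out)
  expect_lt(max(abs(twice$data - out$data)), 1e-12)
})

test_that("bandpass_filter keeps the passband and rejects stopbands", {
  fs <- 128
  t <- (0:2047) / fs
  keep <- sin(2 * pi * 10 * t)
  out <- bandpass_filter(keep, 0.5, 45, fs = fs)
  expect_lt(abs(fft_amplitude(out, 10, fs) / fft_amplitude(keep, 10, fs) - 1),
            0.05)

  drop60 <- sin(2 * pi * 60 * t)
  out60 <- bandpass_filter(drop60, 0.5, 45, fs = fs)
  ratio <- fft_amplitude(out60, 60, fs) / fft_amplitude(drop60, 60, fs)
  expect_lt(20 * log10(ratio), -20)

  # >= 20 dB already at 1.2x the upper edge
  drop54 <- sin(2 * pi * 54 * t)
  out54 <- bandpass_filter(drop54, 0.5, 45, fs = fs)
  expect_lt(20 * log10(fft_amplitude(out54, 54, fs) /
                         fft_amplitude(drop54, 54, fs)), -20)

  expect_equal(bandpass_filter(rep(0, 512), 0.5, 45, fs = fs), rep(0, 512))
  expect_error(bandpass_filter(keep, 0.5, 64, fs = fs), "Nyquist")
})

test_that("double band-pass keeps passband distortion within 2x single pass", {
  fs <- 128
  t <- (0:2047) / fs
  x <- sin(2 * pi * 10 * t)
  once <- bandpass_filter(x, 0.5, 45, fs = fs)
  twice <- bandpass_filter(once, 0.5, 45, fs = fs)
  d1 <- abs(fft_amplitude(once, 10, fs) / fft_amplitude(x, 10, fs) - 1)
  d2 <- abs(fft_amplitude(twice, 10, fs) / fft_amplitude(x, 10, fs) - 1)
  expect_lte(d2, 2 * d1 + 1e-12)
})

test_that("epoch_trials cuts half-open non-overlapping windows", {
  set.seed(6)
  rec <- recording(matrix(rnorm(128 * 75 * 2), ncol = 2), 128, c("a", "b"))
  labels <- rep(0:1, length.out = 25)
  ts <- epoch_trials(rec, 3, labels = labels)
  expect_equal(dim(ts$trials), c(25, 2, 384))
  expect_equal(ts$labels, as.integer(labels))
  # concatenating trials in order reproduces the used prefix exactly
  flat <- do.call(rbind, lapply(1:25, function(tr) t(ts$trials[tr, , ])))
  expect_equal(flat, rec$data[1:(25 * 384), ], ignore_attr = TRUE)
})

test_that("epoch_trials discards remainders with a warning and checks labels", {
  rec <- recording(matrix(rnorm(1280), ncol = 1), 128, "a") # 10 s
  expect_warning(ts <- epoch_trials(rec, 3), "1.00 s")
  expect_equal(dim(ts$trials)[1], 3)
  expect_error(epoch_trials(rec, 3, labels = c(1, 0, 1, 1)),
               "1280 samples available|samples available")
  expect_error(
    epoch_trials(recording(matrix(rnorm(768), ncol = 1), 128, "a"), 3,
                 labels = c(1, 0, 1)),
    "samples available")
})

test_that("trial_crop extracts the stated sub-window", {
  rec <- recording(matrix(seq_len(128 * 6), ncol = 1), 128, "a")
  ts <- epoch_trials(rec, 3, labels = c(0, 1), trial_crop = c(1, 3))
  expect_equal(dim(ts$trials)[3], 256)
  # second 1.0 of each trial starts at sample 128 (0-based)
  expect_equal(ts$trials[1, 1, 1], 129, ignore_attr = TRUE)
  expect_equal(ts$trials[2, 1, 1], 384 + 129, ignore_attr = TRUE)
})
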