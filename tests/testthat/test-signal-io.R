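test_that("EDF round-trip preserves signals to quantization accuracy", {
  g <- generate_segment(regime_spec("interictal", seed = 21))
  path <- tempfile(fileext = ".edf")
  write_edf(g$segment, path)
  rec <- read_edf(path)
  expect_identical(nrow(rec$data), 23L)
  expect_identical(ncol(rec$data), 2560L)
  expect_equal(rec$rate, 256)
  expect_identical(rec$channel_names, scalp_channel_names())
  q <- 2 * max(abs(g$segment$data)) / 65536    # one quantization step
  expect_lt(max(abs(rec$data - g$segment$data)), 1.01 * q)
  unlink(path)
})

test_that("EDF reader rejects bad inputs", {
  expect_error(read_edf(""), "non-empty")
  expect_error(read_edf(tempfile(fileext = ".edf")), "not found")
  # hand-built header with two channels at different rates
  path <- tempfile(fileext = ".edf")
  con <- file(path, "wb")
  pad <- function(s, w) formatC(as.character(s), width = w, flag = "-")
  writeChar(paste0(pad("0", 8), pad("x", 80), pad("x", 80), "01.01.00",
                   "00.00.00", pad(256 * 3, 8), pad("", 44), pad(1, 8),
                   pad(1, 8), pad(2, 4)), con, eos = NULL)
  fld <- function(vals, w) writeChar(paste(vapply(vals, pad, "", w = w),
                                           collapse = ""), con, eos = NULL)
  fld(c("a", "b"), 16); fld(c("", ""), 80); fld(c("uV", "uV"), 8)
  fld(c("-1", "-1"), 8); fld(c("1", "1"), 8)
  fld(c("-32768", "-32768"), 8); fld(c("32767", "32767"), 8)
  fld(c("", ""), 80); fld(c(256, 128), 8); fld(c("", ""), 32)
  writeBin(integer(384), con, size = 2, endian = "little")
  close(con)
  expect_error(read_edf(path), "non-uniform")
  unlink(path)
})

test_that("segmentation yields floor(duration/10) windows and partitions the data", {
  rec <- eeg_recording(matrix(rnorm(23 * 2560 * 2 + 23 * 1280), nrow = 23),
                       rate = 256, id = "toy")   # 25 s
  segs <- segment_recording(rec)
  expect_length(segs, 2L)
  # concatenation reproduces the truncated recording exactly
  expect_identical(unname(cbind(segs[[1]]$data, segs[[2]]$data)),
                   unname(rec$data[, 1:5120]))

  rec10 <- eeg_recording(matrix(rnorm(23 * 2560), nrow = 23), rate = 256)
  expect_length(segment_recording(rec10), 1L)
  rec5 <- eeg_recording(matrix(rnorm(23 * 1280), nrow = 23), rate = 256)
  expect_warning(out <- segment_recording(rec5), "shorter")
  expect_length(out, 0L)
})

test_that("band-pass filter attenuates out-of-band and passes in-band tones", {
  t <- (0:2559) / 256
  rms <- function(x) sqrt(mean(x^2))
  tone <- function(f) {
    d <- matrix(rep(sin(2 * pi * f * t), 23), nrow = 23, byrow = TRUE)
    eeg_segment(d, rate = 256)
  }
  out60 <- bandpass_filter(tone(60))
  # measured stop-band power at 60 Hz for the zero-phase 4th-order design;
  # must agree with the analytic |H(60)|^2 of the squared response
  bf <- signal::butter(4, c(0.5, 40) / 128, type = "pass")
  H <- signal::freqz(bf$b, bf$a, Fs = 256, n = 4096)
  h60 <- abs(H$h[which.min(abs(H$f - 60))])^2
  ratio <- rms(out60$data[1, ]) / rms(tone(60)$data[1, ])
  expect_lt(ratio, 0.02)
  expect_lt(abs(ratio - h60) / h60, 0.3)
  out10 <- bandpass_filter(tone(10))
  expect_lt(abs(rms(out10$data[1, ]) / rms(tone(10)$data[1, ]) - 1), 0.05)
  zero <- bandpass_filter(eeg_segment(matrix(0, 23, 2560), rate = 256))
  expect_identical(max(abs(zero$data)), 0)
  expect_error(bandpass_filter(tone(10), lo = 0.5, hi = 130), "Nyquist")
})

test_that("filtering is linear", {
  set.seed(8)
  x <- eeg_segment(matrix(rnorm(23 * 2560), 23), rate = 256)
  y <- eeg_segment(matrix(rnorm(23 * 2560), 23), rate = 256)
  a <- 2.5; b <- -1.3
  mix <- eeg_segment(a * x$data + b * y$data, rate = 256)
  lhs <- bandpass_filter(mix)$data
  rhs <- a * bandpass_filter(x)$data + b * bandpass_filter(y)$data
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-7)
})

test_that("artifact hook is a no-op and channel contract is enforced", {
  seg <- segment_fixture()$ictal
  expect_identical(remove_artifacts(seg), seg)
  small <- eeg_segment(matrix(rnorm(4 * 2560), 4), rate = 256)
  expect_error(ste_matrix(small), "23 channels")
  expect_silent(ste_matrix(eeg_segment(matrix(rnorm(3 * 2560), 3), rate = 256),
                           allow_other_channels = TRUE))
})

test_that("Welch band fraction localizes narrowband power", {
  t <- (0:2559) / 256
  x <- sin(2 * pi * 2 * t)
  expect_gt(welch_band_fraction(x, 256, c(0.5, 3)), 0.9)
  expect_lt(welch_band_fraction(x, 256, c(14, 30)), 0.05)
})
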