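make_rec <- function(data, rate = 1000) {
  eeg_recording(data, paste0("C", seq_len(nrow(data))), rate, "S1", "NF")
}

test_that("band-pass keeps in-band tones, kills out-of-band tones and DC", {
  t <- seq_len(4000) / 1000
  rec <- make_rec(rbind(sin(2 * pi * 10 * t),
                        sin(2 * pi * 80 * t),
                        rep(3, 4000)))
  out <- bandpass(rec)
  mid <- 1000:3000 # avoid filter edge transients
  amp <- function(ch) max(abs(out$data[ch, mid]))
  expect_gt(amp(1), 0.95)
  expect_lt(amp(1), 1.05)
  expect_lt(amp(2), 0.1)    # 80 Hz: > 90% attenuation
  expect_lt(amp(3), 0.05)   # DC removed
  expect_equal(ncol(out$data), 4000)
  expect_error(bandpass(make_rec(matrix(rnorm(200), 1), rate = 80)),
               "invalid")
})

test_that("artifact rejection excises exactly the offending 1-s segments", {
  set.seed(2)
  dat <- matrix(rnorm(2 * 5000, sd = 10), 2) # within +-50 uV essentially
  dat[abs(dat) > 50] <- 0
  rec <- make_rec(dat)
  clean <- reject_artifacts(rec)
  expect_false(any(clean$mask))
  expect_identical(clean$recording$data, rec$data)

  spiked <- dat
  spiked[2, 3210] <- 200
  res <- reject_artifacts(make_rec(spiked))
  # brute-force scan over every segment maximum
  seg_max <- vapply(1:5, function(s)
    max(abs(spiked[, ((s - 1) * 1000 + 1):(s * 1000)])), numeric(1))
  expect_identical(res$mask, seg_max > 125)
  expect_equal(which(res$mask), 4L)
  expect_equal(ncol(res$recording$data), 4000)
})

test_that("a degenerate threshold flags everything with a warning", {
  set.seed(3)
  rec <- make_rec(matrix(rnorm(2000), 2))
  expect_warning(res <- reject_artifacts(rec, preprocess_config(
    artifact_threshold = 0.01)), "flagged")
  expect_true(all(res$mask))
  expect_equal(ncol(res$recording$data), 0)
})

test_that("downsampling yields floor(n/factor) samples at rate/factor", {
  rec <- make_rec(matrix(rnorm(120000), 1))
  out <- downsample_tenth(rec, 10)
  expect_equal(ncol(out$data), 12000)
  expect_equal(out$rate, 100)
  # factor 1 is the identity
  expect_identical(downsample_tenth(rec, 1)$data, rec$data)
  # floor division
  out2 <- downsample_tenth(make_rec(matrix(rnorm(95), 1)), 10)
  expect_equal(ncol(out2$data), 9)
  expect_error(downsample_tenth(rec, 0), "factor")
})

test_that("anti-aliased downsampling preserves an in-band tone", {
  t <- seq_len(20000) / 1000
  rec <- make_rec(matrix(sin(2 * pi * 5 * t), 1))
  out <- downsample_tenth(rec, 10)
  mid <- 500:1500
  expect_gt(max(abs(out$data[1, mid])), 0.9)
})

test_that("linear detrending removes lines and preserves structure", {
  n <- 1000
  t <- seq_len(n)
  line <- 2 + 0.01 * t
  rec <- make_rec(rbind(line, line + sin(2 * pi * t / 100)))
  out <- detrend_linear(rec)
  expect_lt(max(abs(out$data[1, ])), 1e-9)
  # regression residual oracle for the line + sinusoid channel
  oracle <- residuals(lm(rec$data[2, ] ~ t))
  expect_equal(out$data[2, ], oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
  # idempotent: already detrended input is unchanged
  again <- detrend_linear(out)
  expect_equal(again$data, out$data, tolerance = 1e-10)
})

test_that("downsampling preserves inter-channel lag structure", {
  # delay of 20 samples at 1,000 Hz appears at ~2 at 100 Hz
  des <- synth_design(n_channels = 2, channel_labels = c("F3", "P5"),
                      rate = 1000, duration_samples = 30000, ar_coeff = 0.5,
                      noise_sd = 1, n_subjects = 1, seed = 12,
                      couplings = list(coupling_spec("F3", "P5", 20, 0.6, "EM")))
  rec <- generate_recording(des, "S1", "EM")
  down <- downsample_tenth(rec, 10)
  x <- down$data[1, ]; y <- down$data[2, ]; n <- length(x)
  cc <- vapply(0:6, function(l)
    cor(x[seq_len(n - l)], y[seq_len(n - l) + l]), numeric(1))
  expect_equal(which.max(cc) - 1L, 2L)
})

test_that("full pipeline composes and returns the mask", {
  des <- synth_design(n_channels = 2, channel_labels = c("F3", "P5"),
                      rate = 1000, duration_samples = 12000, ar_coeff = 0.5,
                      noise_sd = 10, n_subjects = 1, seed = 30)
  rec <- generate_recording(des, "S1", "NF")
  out <- preprocess(rec)
  expect_s3_class(out$recording, "eeg_recording")
  expect_equal(out$recording$rate, 100)
  expect_equal(ncol(out$recording$data),
               (12000 - 1000 * sum(out$artifact_mask)) %/% 10)
  expect_lt(max(abs(rowMeans(out$recording$data))), 1e-8)
})
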