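test_that("identical seeds reproduce bit-identical recordings", {
  des <- two_channel_design(seed = 3)
  a <- generate_recording(des, "S1", "EM")
  b <- generate_recording(des, "S1", "EM")
  expect_identical(a$data, b$data)
  # different subject or condition gives a different realization
  expect_false(identical(a$data, generate_recording(des, "S2", "EM")$data))
  expect_false(identical(a$data, generate_recording(des, "S1", "NM")$data))
})

test_that("uncoupled channels with zero AR are near-independent white noise", {
  des <- synth_design(n_channels = 3, channel_labels = c("F3", "F2", "C2"),
                      rate = 100, duration_samples = 5000, ar_coeff = 0,
                      noise_sd = 1, n_subjects = 1, seed = 10)
  rec <- generate_recording(des, "S1", "NF")
  cc <- cor(t(rec$data))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  # white: lag-1 autocorrelation near zero
  a1 <- acf(rec$data[1, ], plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(a1), 0.05)
})

test_that("an active coupling puts the cross-correlogram peak at its delay", {
  des <- two_channel_design(seed = 7, delay = 5L, strength = 0.5, n = 4000L)
  rec <- generate_recording(des, "S1", "EM")
  # brute-force cross-correlogram: corr(F3[t - l], P5[t]) over lags 0..20
  x <- rec$data["F3", ]; y <- rec$data["P5", ]; n <- length(x)
  cc <- vapply(0:20, function(l)
    cor(x[seq_len(n - l)], y[seq_len(n - l) + l]), numeric(1))
  expect_equal(which.max(cc) - 1L, 5L)

  # coupling inactive in NF: correlation at the coupling delay is in the
  # noise band
  rec0 <- generate_recording(des, "S1", "NF")
  x0 <- rec0$data["F3", ]; y0 <- rec0$data["P5", ]
  cc5 <- cor(x0[seq_len(n - 5)], y0[seq_len(n - 5) + 5])
  expect_lt(abs(cc5), 0.06)
})

test_that("generated series are stationary after burn-in", {
  des <- two_channel_design(seed = 5, n = 6000L)
  rec <- generate_recording(des, "S1", "EM")
  # variance in the first and last fifths agrees; no drift beyond the
  # noise envelope
  for (ch in 1:2) {
    v1 <- var(rec$data[ch, 1:1200])
    v2 <- var(rec$data[ch, 4801:6000])
    expect_lt(abs(log(v1 / v2)), log(1.5))
    expect_lt(max(abs(rec$data[ch, ])), 10 * 1)
  }
})

test_that("unstable designs are rejected naming the couplings", {
  expect_error(
    synth_design(n_channels = 2, channel_labels = c("F3", "P5"),
                 rate = 100, duration_samples = 1000, ar_coeff = 0.9,
                 noise_sd = 1,
                 couplings = list(coupling_spec("F3", "P5", 1, 0.8),
                                  coupling_spec("P5", "F3", 1, 0.8)),
                 n_subjects = 1, seed = 1),
    "unstable.*F3->P5", perl = TRUE)
})

test_that("coupling and design validation rejects bad inputs", {
  expect_error(coupling_spec("F3", "F3", 1, 0.5), "differ")
  expect_error(coupling_spec("F3", "P5", 0, 0.5), "delay")
  expect_error(coupling_spec("F3", "P5", 1, 0.5, conditions = "XX"),
               "unknown conditions")
  expect_error(synth_design(n_channels = 2, channel_labels = c("F3", "P5"),
                            duration_samples = 20,
                            couplings = list(coupling_spec("F3", "P5", 50, 0.1)),
                            seed = 1),
               "10 x")
})

test_that("ground-truth graph returns exactly the condition-active edges", {
  des <- synth_design(
    n_channels = 3, channel_labels = c("F3", "C2", "P5"), rate = 100,
    duration_samples = 1000, seed = 1, n_subjects = 1,
    couplings = list(coupling_spec("F3", "P5", 5, 0.5, c("AM", "EM")),
                     coupling_spec("C2", "P5", 3, 0.4, "NF")))
  expect_equal(nrow(ground_truth_graph(des, "AM")), 1)
  expect_equal(ground_truth_graph(des, "AM")$source, "F3")
  expect_equal(ground_truth_graph(des, "NF")$source, "C2")
  expect_equal(nrow(ground_truth_graph(des, "NM")), 0)
  des0 <- two_channel_design(seed = 1)
  expect_equal(nrow(ground_truth_graph(des0, "NF")), 0)
})

test_that("artifact injection pushes ~1% of samples above 100 uV", {
  des <- synth_design(n_channels = 4, channel_labels = montage_1010(4),
                      rate = 100, duration_samples = 20000, ar_coeff = 0.5,
                      noise_sd = 10, n_subjects = 1, seed = 8,
                      inject_artifacts = TRUE)
  rec <- generate_recording(des, "S1", "NF")
  frac <- mean(abs(rec$data) > 100)
  expect_gt(frac, 0.001)
  expect_lt(frac, 0.03)
  # without the flag the amplitude stays in the physiological band
  des0 <- synth_design(n_channels = 4, channel_labels = montage_1010(4),
                       rate = 100, duration_samples = 20000, ar_coeff = 0.5,
                       noise_sd = 10, n_subjects = 1, seed = 8)
  expect_lt(mean(abs(generate_recording(des0, "S1", "NF")$data) > 100), 5e-4)
})

test_that("aliased conditions reuse the partner realization relabelled", {
  des <- scaled_study_design(seed = 4, duration_samples = 300)
  ef <- generate_recording(des, "S1", "EF")
  nf <- generate_recording(des, "S1", "NF")
  expect_identical(ef$data, nf$data)
  expect_equal(ef$condition, "EF")
  expect_equal(nrow(ground_truth_graph(des, "EF")), 0)
})
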