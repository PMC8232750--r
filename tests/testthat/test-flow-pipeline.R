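test_that("pairwise TE recovers a planted coupling as the matrix maximum", {
  des <- synth_design(n_channels = 4,
                      channel_labels = c("F3", "F2", "P5", "P6"), rate = 100,
                      duration_samples = 1500, ar_coeff = 0.5, noise_sd = 1,
                      couplings = list(coupling_spec("F3", "P5", 5, 0.6, "EM")),
                      n_subjects = 1, seed = 77)
  rec <- generate_recording(des, "S1", "EM")
  m <- pairwise_te(rec, te_config(), lag_range = c(0L, 8L))
  expect_equal(diag(m$te), rep(0, 4), ignore_attr = TRUE)
  off <- m$te[row(m$te) != col(m$te)]
  expect_equal(max(off), m$te["F3", "P5"])
  expect_equal(m$lags["F3", "P5"], 5L, ignore_attr = TRUE)
})

test_that("pairwise TE on independent channels stays in the zero band", {
  des <- null_study_design(seed = 5, duration_samples = 800)
  rec <- generate_recording(des, "S1", "NF")
  rec$data <- rec$data[1:3, ]; rec$labels <- rec$labels[1:3]
  m <- pairwise_te(rec, te_config(), lag_range = c(0L, 5L))
  # each entry is a max over 6 noisy near-zero estimates, so the band is
  # wider than a single-lag estimate's
  expect_lt(max(m$te), 0.06)
  # C = 2: exactly two computed entries
  rec2 <- rec; rec2$data <- rec$data[1:2, ]; rec2$labels <- rec$labels[1:2]
  m2 <- pairwise_te(rec2, te_config(), lag_range = c(0L, 2L))
  expect_equal(sum(row(m2$te) != col(m2$te)), 2)
})

test_that("lags convert to milliseconds", {
  expect_equal(lag_to_ms(50, 100), 500)
  expect_equal(lag_to_ms(0, 100), 0)
  expect_equal(lag_to_ms(5, 100), 50)
  expect_error(lag_to_ms(-1, 100), "non-negative")
})

test_that("neutral contrast subtracts element-wise with label checks", {
  lab <- c("F3", "F2", "C2")
  a <- labelled_matrix(0.02, lab)
  b <- labelled_matrix(0.01, lab)
  d <- neutral_contrast(a, b)
  expect_equal(d[row(d) != col(d)], rep(0.01, 6))
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_equal(max(abs(neutral_contrast(a, a))), 0)
  expect_error(neutral_contrast(a, labelled_matrix(0.01, c("F3", "F2", "P5"))),
               "labels")
})

test_that("a condition-specific coupling shows only in its contrast", {
  des <- two_channel_design(seed = 15, delay = 3L, strength = 0.6, n = 1200L,
                            conditions = "EM")
  em <- pairwise_te(generate_recording(des, "S1", "EM"), te_config(),
                    c(0L, 6L))
  nm <- pairwise_te(generate_recording(des, "S1", "NM"), te_config(),
                    c(0L, 6L))
  d <- neutral_contrast(em, nm)
  expect_gt(d["F3", "P5"], 0.05)
  expect_lt(abs(d["P5", "F3"]), 0.05)
})

test_that("grand average is the element-wise mean, order-invariant", {
  lab <- c("F3", "F2")
  m0 <- labelled_matrix(0, lab)
  m2 <- labelled_matrix(0.2, lab)
  expect_equal(grand_average(list(m2)), m2)
  avg <- grand_average(list(m0, m2))
  expect_equal(avg["F3", "F2"], 0.1)
  expect_equal(grand_average(list(m2, m0)), avg)
  expect_error(grand_average(list()), "no matrices")
})

test_that("bootstrap threshold keeps only entries above the mean's upper CI", {
  lab <- paste0("C", 1:10)
  m <- labelled_matrix(0, lab)
  m["C1", "C2"] <- 1.0
  flow <- bootstrap_upper_threshold(m, B = 500, seed = 4)
  expect_gt(flow$threshold, 0)
  expect_equal(sum(flow$surviving != 0), 1)
  expect_equal(flow$surviving["C1", "C2"], 1.0)
  expect_equal(unname(flow$out_degree["C1"]), 1)
  # exhaustive check at small B: threshold is the 97.5th percentile of
  # resampled means of the off-diagonal entries
  off <- m[row(m) != col(m)]
  thr2 <- withr::with_seed(4, {
    bm <- vapply(seq_len(500), function(b)
      mean(off[sample.int(length(off), replace = TRUE)]), numeric(1))
    unname(quantile(bm, 0.975))
  })
  expect_equal(flow$threshold, thr2)
  # same seed protocol reproduces the threshold
  flow2 <- bootstrap_upper_threshold(m, B = 500, seed = 4)
  expect_identical(flow$threshold, flow2$threshold)
})

test_that("degenerate constant matrix: equal-to-threshold entries survive", {
  lab <- paste0("C", 1:5)
  m <- labelled_matrix(0.3, lab)
  expect_message(flow <- bootstrap_upper_threshold(m, B = 200, seed = 1),
                 "degenerate")
  expect_equal(flow$threshold, 0.3)
  expect_equal(unname(flow$out_degree), rep(4, 5))
})

test_that("raising the CI level never increases the surviving count", {
  set.seed(6)
  m <- labelled_matrix(abs(rnorm(64, 0.02, 0.02)), paste0("C", 1:8))
  n90 <- sum(bootstrap_upper_threshold(m, B = 1000, level = 90,
                                       seed = 2)$surviving != 0)
  n95 <- sum(bootstrap_upper_threshold(m, B = 1000, level = 95,
                                       seed = 2)$surviving != 0)
  n99 <- sum(bootstrap_upper_threshold(m, B = 1000, level = 99,
                                       seed = 2)$surviving != 0)
  expect_lte(n95, n90)
  expect_lte(n99, n95)
})

test_that("channel selection keeps only degrees above the bootstrap bound", {
  lab <- paste0("C", 1:4)
  m <- labelled_matrix(0, lab)
  flow <- bootstrap_upper_threshold(m + diag(0, 4), B = 200, seed = 3)
  flow$out_degree <- c(C1 = 10, C2 = 0, C3 = 0, C4 = 0)
  sel <- select_channels(flow, B = 500, seed = 5)
  expect_equal(as.character(sel), "C1")
  # small-B exhaustive: the bound is the 97.5th percentile of resampled
  # degree means, and 10 exceeds any resampled mean of {10,0,0,0}
  expect_lte(attr(sel, "degree_bound"), 10)
  # all-equal degrees: nothing strictly exceeds the bound
  flow$out_degree <- c(C1 = 3, C2 = 3, C3 = 3, C4 = 3)
  expect_length(select_channels(flow, B = 200, seed = 5), 0)
  # all-zero degrees: empty selection is valid
  flow$out_degree <- c(C1 = 0, C2 = 0, C3 = 0, C4 = 0)
  expect_length(select_channels(flow, B = 200, seed = 5), 0)
})

test_that("common channels intersect retained settings and report drops", {
  sel <- list(AF = c("F3", "F2", "C2"), AM = c("F2", "C2", "P5"),
              EF = character(0), EM = c("F2", "C2"))
  cc <- common_channels(sel)
  expect_setequal(cc$common, c("F2", "C2"))
  expect_equal(cc$dropped, "EF")
  expect_setequal(cc$retained, c("AF", "AM", "EM"))
  expect_equal(common_channels(list(A = "F3", B = "F3"))$common, "F3")
  expect_length(common_channels(list(A = "F3", B = "P5"))$common, 0)
  allempty <- common_channels(list(A = character(0), B = character(0)))
  expect_length(allempty$common, 0)
  expect_setequal(allempty$dropped, c("A", "B"))
  expect_error(common_channels(list(A = "F3")), "2 settings")
})

test_that("grand averages and thresholds are subject-order invariant", {
  set.seed(8)
  lab <- paste0("C", 1:6)
  mats <- replicate(5, labelled_matrix(rnorm(36, 0.02, 0.01), lab),
                    simplify = FALSE)
  g1 <- grand_average(mats)
  g2 <- grand_average(rev(mats))
  expect_equal(g1, g2)
  expect_identical(bootstrap_upper_threshold(g1, B = 300, seed = 9)$threshold,
                   bootstrap_upper_threshold(g2, B = 300, seed = 9)$threshold)
})
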