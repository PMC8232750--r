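# Frozen closed-form value for the reference pair x -> y with coupling 0.5,
# AR 0.5, unit innovations, delay 1, histories 1/1. Derived from the
# stationary-covariance algebra and cross-checked below against a plain
# regression plug-in on simulated data.
REF_TE_C05 <- 0.1348318

test_that("Gaussian oracle matches the regression plug-in estimate", {
  orc <- gaussian_te_oracle(var_pair_lagmat(0.5), c(1, 1),
                            source = 1, target = 2, delay = 1)
  expect_equal(orc, REF_TE_C05, tolerance = 1e-6)
  # independent oracle: residual-variance ratio from a long simulation
  set.seed(101)
  d <- sim_var_pair(2e5, 0.5)
  t <- 3:2e5
  v1 <- var(residuals(lm(d$y[t] ~ d$y[t - 1])))
  v2 <- var(residuals(lm(d$y[t] ~ d$y[t - 1] + d$x[t - 1])))
  expect_equal(orc, 0.5 * log(v1 / v2), tolerance = 0.02)
})

test_that("Gaussian oracle obeys structural identities", {
  # zero coupling: conditioning on the source adds nothing
  expect_equal(gaussian_te_oracle(var_pair_lagmat(0), c(1, 1), 1, 2,
                                  delay = 1), 0, tolerance = 1e-12)
  # symmetric bidirectional coupling: TE equal in both directions
  A <- rbind(c(0.4, 0.3), c(0.3, 0.4))
  expect_equal(gaussian_te_oracle(A, c(1, 1), 1, 2, delay = 1),
               gaussian_te_oracle(A, c(1, 1), 2, 1, delay = 1),
               tolerance = 1e-10)
  expect_error(gaussian_te_oracle(rbind(c(1.1, 0), c(0, 0.5)), c(1, 1)),
               "non-stationary")
})

test_that("KSG is near zero for independent and for synchronized pairs", {
  set.seed(42)
  x <- rnorm(4096); y <- rnorm(4096)
  expect_lt(abs(ksg_te(x, y, te_config(delay = 1))$value), 0.02)
  # exact copy: complete synchronization carries no transfer
  z <- as.numeric(arima.sim(list(ar = 0.5), 4096))
  expect_lt(abs(ksg_te(z, z, te_config(delay = 1))$value), 0.02)
})

test_that("KSG tracks the Gaussian oracle on the reference pair", {
  set.seed(7)
  d <- sim_var_pair(20000, 0.5)
  est <- ksg_te(d$x, d$y, te_config(delay = 1))$value
  expect_lt(abs(est - REF_TE_C05) / REF_TE_C05, 0.15)
})

test_that("KSG estimates are monotone in coupling strength and track the
           oracle over the grid", {
  set.seed(21)
  strengths <- c(0.1, 0.3, 0.5)
  oracle <- vapply(strengths, function(c)
    gaussian_te_oracle(var_pair_lagmat(c), c(1, 1), 1, 2, delay = 1),
    numeric(1))
  est <- vapply(strengths, function(c) {
    mean(replicate(4, {
      d <- sim_var_pair(6000, c)
      ksg_te(d$x, d$y, te_config(delay = 1, theiler = 10))$value
    }))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_gt(cor(est, oracle), 0.99)
})

test_that("estimator is deterministic and jitter-invariant", {
  set.seed(3)
  d <- sim_var_pair(2000, 0.5)
  a <- ksg_te(d$x, d$y, te_config(delay = 1))$value
  b <- ksg_te(d$x, d$y, te_config(delay = 1))$value
  expect_identical(a, b)
  c2 <- ksg_te(d$x, d$y, te_config(delay = 1, noise_jitter_sd = 2e-8))$value
  expect_lt(abs(c2 - a) / abs(a), 0.01)
})

test_that("direction matters: driver-to-response exceeds the reverse", {
  set.seed(9)
  wins <- mean(replicate(30, {
    d <- sim_var_pair(1500, 0.5)
    fw <- ksg_te(d$x, d$y, te_config(delay = 1))$value
    bw <- ksg_te(d$y, d$x, te_config(delay = 1))$value
    fw > bw
  }))
  expect_gte(wins, 0.95)
})

test_that("zero law: mean estimate over independent pairs is ~0", {
  set.seed(11)
  v <- replicate(60, ksg_te(rnorm(1024), rnorm(1024),
                            te_config(delay = 1))$value)
  expect_lt(abs(mean(v)), 0.005)
})

test_that("input contracts are enforced", {
  expect_error(ksg_te(rnorm(50), rnorm(50)), "length >= 100")
  expect_error(ksg_te(rnorm(200), rnorm(100)), "equal length")
  expect_error(ksg_te(rep(1, 200), rnorm(200)), "constant")
  expect_error(ksg_te(rnorm(200), rnorm(200),
                      te_config(delay = 300)), "too short")
})

test_that("lag scan recovers the generative delay and reports the scan", {
  des <- two_channel_design(seed = 31, delay = 5L, strength = 0.5, n = 2000L)
  rec <- generate_recording(des, "S1", "EM")
  r <- lag_scan_te(rec$data[1, ], rec$data[2, ], te_config(), 0, 15)
  expect_equal(r$delay_used, 5L)
  expect_length(attr(r, "scan"), 16)
  expect_equal(unname(attr(r, "scan")["5"]), r$value)
})

test_that("degenerate single-candidate scan equals a direct estimate", {
  set.seed(13)
  d <- sim_var_pair(1200, 0.5)
  scan <- lag_scan_te(d$x, d$y, te_config(), lag_min = 3, lag_max = 3)
  direct <- ksg_te(d$x, d$y, te_config(delay = 3))
  expect_equal(scan$value, direct$value)
  expect_equal(scan$delay_used, 3L)
  expect_error(lag_scan_te(d$x, d$y, te_config(), 5, 2), "lag_min")
})

test_that("independent series give a low maximal TE across the scan", {
  set.seed(17)
  r <- lag_scan_te(rnorm(1500), rnorm(1500), te_config(), 0, 10)
  # the scan maximum over 11 near-zero estimates sits above a single
  # estimate's band
  expect_lt(r$value, 0.03)
})

test_that("nats convert to bits", {
  expect_equal(nats_to_bits(log(2)), 1)
  expect_equal(nats_to_bits(0), 0)
})
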