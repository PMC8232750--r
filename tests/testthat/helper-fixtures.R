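# Shared fixtures built in code.

# Bivariate AR(1) pair: x drives y with coefficient `c` at lag 1.
sim_var_pair <- function(n, c, a = 0.5) {
  x <- as.numeric(stats::filter(rnorm(n), a, method = "recursive"))
  e <- rnorm(n)
  y <- as.numeric(stats::filter(c * c(0, x[-n]) + e, a, method = "recursive"))
  list(x = x, y = y)
}

# Coefficient matrices for the pair above (channel 1 = x, channel 2 = y).
var_pair_lagmat <- function(c, a = 0.5) rbind(c(a, 0), c(c, a))

# Two-channel design with a single directed coupling, generated directly at
# the 100 Hz analysis rate.
two_channel_design <- function(seed, delay = 5L, strength = 0.5,
                               n = 2000L, conditions = "EM") {
  synth_design(n_channels = 2, channel_labels = c("F3", "P5"), rate = 100,
               duration_samples = n, ar_coeff = 0.5, noise_sd = 1,
               couplings = list(
                 coupling_spec("F3", "P5", delay, strength, conditions)),
               n_subjects = 1, seed = seed)
}

# Small labelled square matrix for pipeline unit tests.
labelled_matrix <- function(values, labels) {
  m <- matrix(values, length(labels), length(labels),
              dimnames = list(labels, labels))
  diag(m) <- 0
  m
}
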