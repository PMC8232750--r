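#' Transfer-entropy estimator configuration
#'
#' @param k_neighbors number of nearest neighbours for the KSG estimator
#'   (default 4).
#' @param history_source,history_target embedding lengths for the source and
#'   target pasts (defaults 1/1; the estimator's adaptive kernel width is
#'   parameter-free, the embedding is not, so it is fixed and explicit).
#' @param delay source-target lag mu in samples (>= 0). `TE(X -> Y, mu)` is
#'   the conditional mutual information `I(Y_t ; X_{t-mu} | Y_past)`, so a
#'   generative coupling `y_t ~ x_{t-d}` attains its maximum at `mu = d`;
#'   `mu = 0` pairs the source sample simultaneous with the target future.
#' @param noise_jitter_sd SD of the deterministic tie-breaking jitter added
#'   to the standardized series (default 1e-8).
#' @param theiler dynamic-correlation exclusion window in samples: temporal
#'   neighbours within `theiler` samples are excluded from the neighbour
#'   search and counts, so serially correlated samples do not masquerade as
#'   independent neighbours (default 0, i.e. off).
#' @return object of class `te_config`.
#' @export
te_config <- function(k_neighbors = 4L, history_source = 1L,
                      history_target = 1L, delay = 1L,
                      noise_jitter_sd = 1e-8, theiler = 0L) {
  stopifnot(k_neighbors >= 1, history_source >= 1, history_target >= 1,
            delay >= 0, noise_jitter_sd > 0, theiler >= 0)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 history_source = as.integer(history_source),
                 history_target = as.integer(history_target),
                 delay = as.integer(delay),
                 noise_jitter_sd = noise_jitter_sd,
                 theiler = as.integer(theiler)),
            class = "te_config")
}

# Content-derived 31-bit seed so jitter (and hence the estimate) is a pure
# function of the data. Each series seeds its own jitter: identical series
# receive identical jitter, so duplicated coordinates (e.g. a target that is
# an exact copy of the source, where the source embedding equals the target
# history) stay exactly tied and their neighbour counts cancel, recovering
# the theoretical zero for fully synchronized processes.
content_seed <- function(x) {
  h <- 104729
  for (v in c(head(x, 64), length(x))) {
    h <- (h * 31 + abs(v) * 1e6) %% 2147483647
  }
  as.integer(floor(h))
}

# Time-delay embedding for TE(X -> Y, mu): rows index the target future Y_t;
# S holds X_{t-mu}, ..., X_{t-mu-hx+1}; Z holds Y_{t-1}, ..., Y_{t-hy}.
te_embed <- function(x, y, cfg) {
  n <- length(x)
  hx <- cfg$history_source; hy <- cfg$history_target; mu <- cfg$delay
  t0 <- max(hy + 1L, mu + hx)
  if (t0 + 1L > n) {
    stop("series too short: need length > ", t0,
         " for delay ", mu, " and histories (", hx, ", ", hy, ")")
  }
  t <- seq.int(t0 + 1L, n)
  S <- vapply(seq_len(hx), function(l) x[t - mu - l + 1L], numeric(length(t)))
  Z <- vapply(seq_len(hy), function(l) y[t - l], numeric(length(t)))
  list(f = y[t], S = matrix(S, ncol = hx), Z = matrix(Z, ncol = hy))
}

#' KSG transfer entropy between two series
#'
#' Estimates `TE(X -> Y)` in nats as the conditional mutual information
#' `I(Y_t ; X_{t-mu} | Y_{t-1..t-hy})` with the Kraskov-Stoegbauer-Grassberger
#' nearest-neighbour estimator (max-norm, digamma-corrected neighbour counts).
#' Both series are standardized internally (TE is invariant to monotone
#' linear rescaling) and a tiny deterministic jitter breaks distance ties.
#' The contract is strictly non-symmetric: `ksg_te(x, y)` and `ksg_te(y, x)`
#' are independent quantities.
#'
#' @param x source series.
#' @param y target series (same length, >= 100 samples).
#' @param cfg a [te_config].
#' @return list of class `te_result`: `value` (nats), `delay_used`,
#'   `n_vectors`.
#' @export
ksg_te <- function(x, y, cfg = te_config()) {
  stopifnot(inherits(cfg, "te_config"))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 100) stop("series must have length >= 100")
  sx <- sd(x); sy <- sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    stop("constant or non-finite series: transfer entropy undefined")
  }
  xs <- add_jitter_cpp((x - mean(x)) / sx, cfg$noise_jitter_sd,
                       content_seed(x))
  ys <- add_jitter_cpp((y - mean(y)) / sy, cfg$noise_jitter_sd,
                       content_seed(y))
  emb <- te_embed(xs, ys, cfg)
  if (cfg$k_neighbors >= length(emb$f)) {
    stop("k_neighbors must be < number of usable sample vectors (",
         length(emb$f), ")")
  }
  value <- ksg_cmi_cpp(emb$f, emb$S, emb$Z, cfg$k_neighbors, cfg$theiler)
  structure(list(value = value, delay_used = cfg$delay,
                 n_vectors = length(emb$f)),
            class = "te_result")
}

#' @export
print.te_result <- function(x, ...) {
  cat(sprintf("TE = %.5f nats (delay %d, %d vectors)\n",
              x$value, x$delay_used, x$n_vectors))
  invisible(x)
}

#' Brute-force information-transfer-delay scan
#'
#' Evaluates [ksg_te] at every integer delay in `[lag_min, lag_max]` and
#' returns the maximum: for coupled processes the maximizing lag estimates
#' the true information-transfer delay. Ties break toward the smaller delay.
#'
#' @param x,y source and target series.
#' @param cfg a [te_config]; its `delay` field is overridden by the scan.
#' @param lag_min,lag_max inclusive delay range in samples (defaults 0--50).
#' @return `te_result` with the maximal `value` and its `delay_used`;
#'   attribute `"scan"` holds the full per-lag TE vector.
#' @export
lag_scan_te <- function(x, y, cfg = te_config(), lag_min = 0L, lag_max = 50L) {
  if (lag_min > lag_max) stop("lag_min must be <= lag_max")
  lags <- seq.int(lag_min, lag_max)
  values <- vapply(lags, function(mu) {
    cfg$delay <- as.integer(mu)
    ksg_te(x, y, cfg)$value
  }, numeric(1))
  best <- which.max(values) # which.max takes the first maximum: smaller delay
  cfg$delay <- as.integer(lags[best])
  out <- ksg_te(x, y, cfg)
  out$value <- values[best]
  attr(out, "scan") <- stats::setNames(values, lags)
  out
}

#' Convert nats to bits
#' @param nats value in natural-log units.
#' @export
nats_to_bits <- function(nats) nats / log(2)

#' Closed-form Gaussian transfer entropy for a linear VAR process
#'
#' For a stationary linear-Gaussian VAR, transfer entropy has the closed form
#' `0.5 * ln( Var(Y_t | Y_past) / Var(Y_t | Y_past, X_past) )`, with both
#' conditional variances computed analytically from the stationary
#' covariance (discrete Lyapunov equation on the companion form). Serves as
#' the calibration oracle for the KSG estimator on linear designs.
#'
#' @param lag_mats list of C x C coefficient matrices, element `l` holding
#'   the lag-`l` coefficients (entry `(i, j)` drives channel `i` from
#'   channel `j`).
#' @param noise_cov innovation covariance (C x C) or a vector of variances.
#' @param source,target channel indices (source drives target).
#' @param histories integer pair `c(hx, hy)`, source/target embedding
#'   lengths as in [te_config].
#' @param delay source-target lag mu (>= 0), same convention as [te_config].
#' @return transfer entropy in nats (>= 0).
#' @export
gaussian_te_oracle <- function(lag_mats, noise_cov, source = 1L, target = 2L,
                               histories = c(1L, 1L), delay = 1L) {
  if (is.matrix(lag_mats)) lag_mats <- list(lag_mats)
  C <- nrow(lag_mats[[1]])
  if (!is.matrix(noise_cov)) noise_cov <- diag(noise_cov, C)
  comp <- companion_matrix(lag_mats)
  D <- nrow(comp)
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1) stop("non-stationary coefficients (spectral radius >= 1)")
  Q <- matrix(0, D, D)
  Q[seq_len(C), seq_len(C)] <- noise_cov
  # Solve Sigma = A Sigma A' + Q via vec().
  Sig <- matrix(solve(diag(D * D) - kronecker(comp, comp), as.vector(Q)), D, D)
  Sig <- (Sig + t(Sig)) / 2

  hx <- histories[1]; hy <- histories[2]; mu <- delay
  max_h <- max(hy, mu + hx - 1L)
  # Gamma(h) = Cov(x_t, x_{t-h}) for the C-dim process: top-left block of
  # comp^h %*% Sig.
  gam <- vector("list", max_h + 1L)
  Ah <- diag(D)
  for (h in 0:max_h) {
    gam[[h + 1L]] <- (Ah %*% Sig)[seq_len(C), seq_len(C), drop = FALSE]
    Ah <- comp %*% Ah
  }
  cv <- function(ci, hi, cj, hj) { # Cov(chan ci at lag hi, chan cj at lag hj)
    h <- hi - hj
    if (h >= 0) gam[[h + 1L]][cj, ci] else gam[[-h + 1L]][ci, cj]
  }
  # Stacked vector: y_t, then y-past lags 1..hy, then x at lags mu..mu+hx-1.
  vars <- rbind(
    c(target, 0L),
    cbind(target, seq_len(hy)),
    cbind(source, mu + seq_len(hx) - 1L)
  )
  m <- nrow(vars)
  V <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    V[i, j] <- cv(vars[j, 1], vars[j, 2], vars[i, 1], vars[i, 2])
  }
  V <- (V + t(V)) / 2
  cond_var <- function(idx) {
    S11 <- V[1, 1]
    S12 <- V[1, idx, drop = FALSE]
    S22 <- V[idx, idx, drop = FALSE]
    drop(S11 - S12 %*% solve(S22, t(S12)))
  }
  v_y <- cond_var(1L + seq_len(hy))
  v_xy <- cond_var(1L + seq_len(hy + hx))
  max(0, 0.5 * log(v_y / v_xy))
}
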