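#' Rosenthal effect size from a standardized statistic
#'
#' r = W / sqrt(N) for a standardized Wilcoxon statistic, or
#' r = sqrt(chi2 / N) for a Kruskal-Wallis chi-square, with `N` the total
#' sample size.
#'
#' @param statistic standardized Wilcoxon `W` (z-like) or chi-square `H`.
#' @param n total sample size.
#' @param type `"rank"` (Wilcoxon, signed result) or `"chisq"`
#'   (Kruskal-Wallis, non-negative result).
#' @export
rosenthal_r <- function(statistic, n, type = c("rank", "chisq")) {
  type <- match.arg(type)
  stopifnot(n > 0)
  if (type == "rank") statistic / sqrt(n) else sqrt(statistic / n)
}

#' Classify a nonparametric effect size
#'
#' Magnitude of `|r|`: small when r <= 0.3, medium when 0.3 < r < 0.5,
#' large when r >= 0.5.
#'
#' @param r effect size (finite; absolute value is classified).
#' @export
classify_effect <- function(r) {
  stopifnot(is.finite(r))
  a <- abs(r)
  if (a <= 0.3) "small" else if (a < 0.5) "medium" else "large"
}

group_test_result <- function(test, statistic, df, p, effect_r, extra = list()) {
  structure(c(list(test = test, statistic = statistic, df = df, p = p,
                   effect_r = effect_r,
                   magnitude = classify_effect(effect_r)), extra),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  p_txt <- if (x$p < 0.001) "p < 0.001" else sprintf("p = %.3f", x$p)
  cat(sprintf("%s: statistic = %.3f (df %s), %s, r = %.3f (%s)\n",
              x$test, x$statistic, paste(x$df, collapse = ", "), p_txt,
              x$effect_r, x$magnitude))
  invisible(x)
}

#' Lilliefors normality test with Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov distance of the sample against a normal with the
#' sample's estimated mean and SD; the null distribution of the distance
#' (which is not the classical KS null because the parameters are estimated)
#' is approximated by `B_mc` seeded Monte-Carlo replicates of the same
#' statistic on standard-normal samples of equal size.
#'
#' @param sample numeric vector, n >= 4, non-constant.
#' @param B_mc Monte-Carlo replicates (default 2,000).
#' @param seed integer seed.
#' @return `group_test_result` (statistic = KS distance; `effect_r` carries
#'   the distance for magnitude bookkeeping).
#' @export
lilliefors_mc <- function(sample, B_mc = 2000L, seed = 1L) {
  n <- length(sample)
  if (n < 4) stop("need n >= 4")
  if (sd(sample) == 0) stop("constant sample: normality test undefined")
  d_obs <- lilliefors_stat(sample)
  d_null <- withr_seed(seed, {
    vapply(seq_len(B_mc), function(b) lilliefors_stat(rnorm(n)), numeric(1))
  })
  p <- (1 + sum(d_null >= d_obs)) / (B_mc + 1)
  group_test_result("lilliefors_mc", d_obs, n, p, d_obs,
                    extra = list(B_mc = B_mc, seed = seed))
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p_hat <- pnorm(z)
  max(seq_len(n) / n - p_hat, p_hat - (seq_len(n) - 1) / n)
}

#' Kruskal-Wallis test with Rosenthal effect size
#'
#' Rank-based H with tie correction (via [stats::kruskal.test]); effect size
#' r = sqrt(H / N) with `N` the total number of observations. Degrees of
#' freedom are reported in the `(k - 1, N - 1)` printing style.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return `group_test_result`.
#' @export
kruskal_wallis_r <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  N <- sum(lengths(groups))
  kt <- kruskal.test(groups)
  H <- unname(kt$statistic)
  group_test_result("kruskal_wallis", H,
                    c(length(groups) - 1L, N - 1L), kt$p.value,
                    rosenthal_r(H, N, "chisq"),
                    extra = list(n = N))
}

#' Wilcoxon tests with standardized statistic and Rosenthal effect size
#'
#' The reported statistic `W` is the standardized (z-like) value of the rank
#' statistic under the normal approximation with tie and continuity
#' correction -- the form whose magnitude is commensurate with printed values
#' like W = -7.99 at hundreds of observations. Effect size r = W / sqrt(N)
#' with `N = n1 + n2` for the rank-sum test and the number of pairs for the
#' signed-rank test. P-values are two-sided.
#'
#' @param a first sample (rank-sum) or paired differences / first member of
#'   the pair (signed-rank).
#' @param b second sample (rank-sum) or second member of the pair
#'   (signed-rank); omit `b` to treat `a` as precomputed differences.
#' @param mode `"ranksum"` or `"signed_rank"`.
#' @param mu null shift for the signed-rank test (default 0).
#' @return `group_test_result` (df reported as `N - 2` for rank-sum and
#'   `N - 1` for signed-rank, matching the conventional printing).
#' @export
wilcoxon_r <- function(a, b = NULL, mode = c("ranksum", "signed_rank"),
                       mu = 0) {
  mode <- match.arg(mode)
  if (mode == "ranksum") {
    if (is.null(b)) stop("ranksum mode needs two samples")
    n1 <- length(a); n2 <- length(b); N <- n1 + n2
    rk <- rank(c(a, b))
    W1 <- sum(rk[seq_len(n1)])
    mu_w <- n1 * (N + 1) / 2
    ties <- table(rk)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) stop("all observations tied: rank-sum test undefined")
    z <- (W1 - mu_w - sign(W1 - mu_w) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    group_test_result("ranksum", z, N - 2L, min(1, p),
                      rosenthal_r(z, N, "rank"), extra = list(n = N))
  } else {
    d <- if (is.null(b)) a - mu else a - b - mu
    d <- d[d != 0]
    if (!length(d)) stop("all paired differences zero: signed-rank undefined")
    n <- length(d)
    rk <- rank(abs(d))
    Wp <- sum(rk[d > 0])
    mu_w <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (Wp - mu_w - sign(Wp - mu_w) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    N <- if (is.null(b)) length(a) else length(a) # pairs incl. zeros
    group_test_result("signed_rank", z, N - 1L, min(1, p),
                      rosenthal_r(z, N, "rank"), extra = list(n = N))
  }
}
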