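#' Effect-size conversion chain from Cohen's f
#'
#' Closed-form conversions linking the ANOVA effect-size scales:
#' `eta^2 = f^2 / (1 + f^2)`, `d = 2 f`, r = d / sqrt(d^2 + 4).
#'
#' @param f Cohen's f (>= 0).
#' @return list: `f`, `eta_squared`, `cohens_d`, `r_equiv`.
#' @export
convert_f <- function(f) {
  if (!is.numeric(f) || f < 0) stop("f must be >= 0")
  d <- 2 * f
  list(f = f,
       eta_squared = f^2 / (1 + f^2),
       cohens_d = d,
       r_equiv = d / sqrt(d^2 + 4))
}

#' Repeated-measures ANOVA power at a given Cohen's f
#'
#' Noncentral-F power for the within-subjects effect under the
#' repeated-measures convention `lambda = f^2 * n * m / (1 - rho)` with
#' numerator df `m - 1` and error df `(n - n_groups) * (m - 1)` (no
#' nonsphericity correction).
#'
#' @param f Cohen's f.
#' @param alpha type-I error level.
#' @param n_total total sample size.
#' @param n_groups number of between-subject groups.
#' @param n_measurements number of repeated measurements m.
#' @param rho correlation among repeated measures, in (-1, 1).
#' @return power in (0, 1).
#' @export
rm_anova_power <- function(f, alpha = 0.05, n_total = 20, n_groups = 2,
                           n_measurements = 6, rho = 0.4) {
  stopifnot(alpha > 0, alpha < 1, n_total > n_groups, n_measurements >= 2,
            rho > -1, rho < 1)
  df1 <- n_measurements - 1
  df2 <- (n_total - n_groups) * (n_measurements - 1)
  lambda <- f^2 * n_total * n_measurements / (1 - rho)
  crit <- qf(1 - alpha, df1, df2)
  1 - pf(crit, df1, df2, ncp = lambda)
}

#' Smallest detectable effect size (sensitivity analysis)
#'
#' Root-finds the Cohen's f at which the repeated-measures design attains
#' the target power at level `alpha`: the smallest effect detectable as
#' significant given the fixed sample size.
#'
#' @inheritParams rm_anova_power
#' @param power target power (e.g. 0.8 for beta = 0.2).
#' @return list of class `sensitivity_result`: `f` plus its conversion chain
#'   ([convert_f]) and the design parameters.
#' @export
min_detectable_f <- function(alpha = 0.05, power = 0.8, n_total = 20,
                             n_groups = 2, n_measurements = 6, rho = 0.4) {
  stopifnot(power > alpha, power < 1)
  g <- function(f) rm_anova_power(f, alpha, n_total, n_groups,
                                  n_measurements, rho) - power
  if (g(50) < 0) stop("target power unattainable in this design")
  f <- uniroot(g, c(1e-8, 50), tol = 1e-10)$root
  structure(c(convert_f(f),
              list(alpha = alpha, power = power, n_total = n_total,
                   n_groups = n_groups, n_measurements = n_measurements,
                   rho = rho)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "Smallest detectable effect (alpha %.3g, power %.3g, n %d, %d x %d, rho %.2f):\n",
    x$alpha, x$power, x$n_total, x$n_groups, x$n_measurements, x$rho))
  cat(sprintf("  f = %.3f  eta^2 = %.3f  d = %.3f  r = %.3f\n",
              x$f, x$eta_squared, x$cohens_d, x$r_equiv))
  invisible(x)
}
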