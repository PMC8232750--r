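#' Directed coupling between two channels
#'
#' A ground-truth edge for the surrogate-EEG generator: `target` receives
#' `strength * source[t - delay]` (optionally squashed through `tanh`) in the
#' conditions where the coupling is active.
#'
#' @param source,target channel labels (must differ).
#' @param delay integer lag in samples at the generation rate (>= 1).
#' @param strength finite coupling coefficient.
#' @param conditions character vector of condition labels in which the edge
#'   is active (subset of [CONDITIONS]).
#' @return object of class `coupling_spec`.
#' @export
coupling_spec <- function(source, target, delay, strength,
                          conditions = CONDITIONS) {
  if (identical(source, target)) stop("source and target must differ")
  if (delay < 1 || delay != round(delay)) stop("delay must be an integer >= 1")
  if (!is.finite(strength)) stop("strength must be finite")
  bad <- setdiff(conditions, CONDITIONS)
  if (length(bad)) stop("unknown conditions: ", paste(bad, collapse = ", "))
  structure(list(source = source, target = target, delay = as.integer(delay),
                 strength = strength, conditions = conditions),
            class = "coupling_spec")
}

#' Surrogate-EEG study design
#'
#' Defines a population of multichannel recordings: each channel follows an
#' order-1 autoregression driven by Gaussian innovations, plus the directed
#' coupling terms active in the generated condition. Defaults emulate the
#' acquisition geometry of a 62-channel active-cap recording at 1,000 Hz
#' with 120,000 samples (2 min) per setting.
#'
#' @param n_channels number of channels (default 62).
#' @param channel_labels labels; default the first `n_channels` 10-10 names.
#' @param rate sampling rate in Hz.
#' @param duration_samples samples kept after burn-in.
#' @param ar_coeff per-channel AR(1) coefficient, |a| < 1; recycled.
#' @param noise_sd per-channel innovation SD in µV (> 0); recycled.
#' @param couplings list of [coupling_spec] objects.
#' @param n_subjects number of subjects the design describes.
#' @param seed master seed; per-(subject, condition) streams derive from it.
#' @param nonlinear if `TRUE` coupling inputs pass through `tanh`, exercising
#'   the estimator's model-free claim; off by default so the linear case
#'   admits the Gaussian closed-form oracle.
#' @param inject_artifacts if `TRUE`, sparse high-amplitude (> 125 µV)
#'   excursions are added so ~1% of samples exceed 100 µV, exercising the
#'   amplitude-based artifact rejection rule.
#' @param condition_alias named character vector declaring conditions that
#'   are exact re-labelings of another condition (e.g. `c(EF = "NF")`):
#'   the aliased condition reuses the partner's realization, modeling a
#'   manipulation with no effect whatsoever, so downstream contrasts are
#'   identically zero. Used to exercise the degenerate empty-selection path
#'   deterministically.
#' @return object of class `synth_design`.
#' @export
synth_design <- function(n_channels = 62,
                         channel_labels = montage_1010(n_channels),
                         rate = 1000,
                         duration_samples = 120000,
                         ar_coeff = 0.5,
                         noise_sd = 10,
                         couplings = list(),
                         n_subjects = 20,
                         seed = 1L,
                         nonlinear = FALSE,
                         inject_artifacts = FALSE,
                         condition_alias = character(0)) {
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (length(channel_labels) != n_channels) stop("labels must match n_channels")
  ar_coeff <- rep_len(ar_coeff, n_channels)
  noise_sd <- rep_len(noise_sd, n_channels)
  if (any(abs(ar_coeff) >= 1)) stop("|ar_coeff| < 1 required for stationarity")
  if (any(noise_sd <= 0)) stop("noise_sd must be > 0")
  for (cp in couplings) {
    if (!inherits(cp, "coupling_spec")) stop("couplings must be coupling_spec")
    if (!all(c(cp$source, cp$target) %in% channel_labels)) {
      stop("coupling ", cp$source, "->", cp$target, " uses unknown labels")
    }
  }
  max_delay <- if (length(couplings)) max(vapply(couplings, `[[`, 1L, "delay")) else 1L
  if (duration_samples < 10 * max_delay) {
    stop("duration_samples must be >= 10 x the maximum coupling delay")
  }
  design <- structure(
    list(n_channels = n_channels, channel_labels = channel_labels, rate = rate,
         duration_samples = as.integer(duration_samples), ar_coeff = ar_coeff,
         noise_sd = noise_sd, couplings = couplings,
         n_subjects = n_subjects, seed = as.integer(seed),
         nonlinear = nonlinear, inject_artifacts = inject_artifacts,
         condition_alias = condition_alias,
         max_delay = as.integer(max_delay)),
    class = "synth_design")
  check_design_stable(design)
  design
}

# Spectral radius of the companion matrix of the implied linear VAR(p).
# The tanh nonlinearity has unit slope at the origin, so the same check
# governs local stability of the nonlinear variant.
check_design_stable <- function(design) {
  C <- design$n_channels
  p <- max(1L, design$max_delay)
  lag_mats <- replicate(p, matrix(0, C, C), simplify = FALSE)
  diag(lag_mats[[1]]) <- design$ar_coeff
  idx <- stats::setNames(seq_len(C), design$channel_labels)
  for (cp in design$couplings) {
    lag_mats[[cp$delay]][idx[[cp$target]], idx[[cp$source]]] <-
      lag_mats[[cp$delay]][idx[[cp$target]], idx[[cp$source]]] + cp$strength
  }
  comp <- companion_matrix(lag_mats)
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1) {
    offenders <- vapply(design$couplings, function(cp)
      paste0(cp$source, "->", cp$target, " (delay ", cp$delay,
             ", strength ", cp$strength, ")"), character(1))
    stop("design is unstable (VAR spectral radius ", signif(rho, 4),
         " >= 1); couplings: ",
         if (length(offenders)) paste(offenders, collapse = "; ")
         else "none (check ar_coeff)")
  }
  invisible(rho)
}

companion_matrix <- function(lag_mats) {
  C <- nrow(lag_mats[[1]]); p <- length(lag_mats)
  comp <- matrix(0, C * p, C * p)
  for (l in seq_len(p)) comp[seq_len(C), (l - 1) * C + seq_len(C)] <- lag_mats[[l]]
  if (p > 1) {
    comp[C + seq_len(C * (p - 1)), seq_len(C * (p - 1))] <-
      diag(C * (p - 1))
  }
  comp
}

# Counter-style substream seed: subjects are exchangeable but each
# (subject, condition) pair maps to a fixed, collision-unlikely 31-bit seed.
substream_seed <- function(master, subject_id, condition) {
  # double-precision modular arithmetic: 31 * (2^31 - 1) < 2^53, so the
  # products stay exact
  s <- as.numeric(master) %% 2147483647
  for (tok in c(as.character(subject_id), condition)) {
    for (ch in utf8ToInt(tok)) {
      s <- (s * 31 + ch) %% 2147483647
    }
  }
  as.integer(s)
}

#' Generate one surrogate recording
#'
#' Simulates the design's VAR process for `subject_id` under `condition`:
#' every channel is an AR(1) process plus the condition-active coupling terms
#' at their stated delays plus Gaussian innovations. A burn-in of
#' `max(10 x max delay, 500)` samples is discarded so the returned series is
#' stationary. Identical `(design, subject_id, condition)` inputs reproduce
#' the identical matrix.
#'
#' @param design a [synth_design].
#' @param subject_id subject identifier.
#' @param condition condition label to generate.
#' @return an [eeg_recording].
#' @export
generate_recording <- function(design, subject_id, condition = "baseline") {
  stopifnot(inherits(design, "synth_design"))
  if (!condition %in% c(CONDITIONS, "baseline")) {
    stop("unknown condition: ", condition)
  }
  if (condition %in% names(design$condition_alias)) {
    out <- generate_recording(design, subject_id,
                              design$condition_alias[[condition]])
    out$condition <- condition
    return(out)
  }
  check_design_stable(design)
  C <- design$n_channels
  burn <- max(10L * design$max_delay, 500L)
  n_tot <- design$duration_samples + burn
  active <- Filter(function(cp) condition %in% cp$conditions, design$couplings)
  idx <- stats::setNames(seq_len(C), design$channel_labels)

  seed <- substream_seed(design$seed, subject_id, condition)
  x <- withr_seed(seed, {
    eps <- matrix(rnorm(C * n_tot, sd = design$noise_sd), nrow = C)
    x <- matrix(0, C, n_tot)
    a <- design$ar_coeff
    start <- design$max_delay + 1L
    x[, seq_len(start - 1L)] <- eps[, seq_len(start - 1L)]
    for (t in start:n_tot) {
      xt <- a * x[, t - 1L] + eps[, t]
      for (cp in active) {
        src <- x[idx[[cp$source]], t - cp$delay]
        if (design$nonlinear) src <- tanh(src)
        xt[idx[[cp$target]]] <- xt[idx[[cp$target]]] + cp$strength * src
      }
      x[, t] <- xt
    }
    x <- x[, (burn + 1L):n_tot, drop = FALSE]
    if (design$inject_artifacts) x <- inject_artifacts(x)
    x
  })
  eeg_recording(x, design$channel_labels, design$rate,
                subject_id = as.character(subject_id), condition = condition)
}

# Evaluate expr under a local RNG state; restores the caller's stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Add sparse high-amplitude excursions (ocular/movement-like) so roughly 1%
# of samples exceed 100 µV; each event is a 100-sample half-sine of 150-250 µV
# on a random channel.
inject_artifacts <- function(x) {
  n <- ncol(x); C <- nrow(x)
  ev_len <- min(100L, n)
  n_events <- max(1L, round(0.01 * n / ev_len))
  for (e in seq_len(n_events)) {
    ch <- sample.int(C, 1)
    at <- sample.int(n - ev_len + 1L, 1)
    amp <- runif(1, 150, 250) * sample(c(-1, 1), 1)
    x[ch, at:(at + ev_len - 1L)] <-
      x[ch, at:(at + ev_len - 1L)] + amp * sin(seq(0, pi, length.out = ev_len))
  }
  x
}

#' Ground-truth directed graph for a condition
#'
#' The recovery oracle: exactly the condition-active couplings of the design.
#'
#' @param design a [synth_design].
#' @param condition condition label.
#' @return data.frame with columns `source`, `target`, `delay`, `strength`
#'   (zero rows when no coupling is active).
#' @export
ground_truth_graph <- function(design, condition) {
  stopifnot(inherits(design, "synth_design"))
  if (!condition %in% c(CONDITIONS, "baseline")) {
    stop("unknown condition: ", condition)
  }
  if (condition %in% names(design$condition_alias)) {
    condition <- design$condition_alias[[condition]]
  }
  active <- Filter(function(cp) condition %in% cp$conditions, design$couplings)
  data.frame(
    source = vapply(active, `[[`, character(1), "source"),
    target = vapply(active, `[[`, character(1), "target"),
    delay = vapply(active, `[[`, integer(1), "delay"),
    strength = vapply(active, `[[`, numeric(1), "strength"),
    stringsAsFactors = FALSE
  )
}
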