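#' All-pairs lag-optimized transfer-entropy matrices
#'
#' For every ordered channel pair of a (preprocessed) recording, runs the
#' brute-force delay scan and stores the maximal TE and its delay, yielding
#' the C x C directed-flow matrix (entry `(i, j)` = TE from channel `i` to
#' channel `j`) and the matching integer lag matrix. Diagonals are zero by
#' convention.
#'
#' @param rec an [eeg_recording] (already conditioned).
#' @param te_cfg a [te_config].
#' @param lag_range integer pair, inclusive delay-scan bounds in samples.
#' @return list of class `te_matrices`: `te` (C x C, nats), `lags` (C x C,
#'   samples), `labels`, `condition`, `subject`, `rate`.
#' @export
pairwise_te <- function(rec, te_cfg = te_config(), lag_range = c(0L, 50L)) {
  stopifnot(inherits(rec, "eeg_recording"))
  C <- nrow(rec$data)
  if (C < 2) stop("need at least 2 channels")
  te <- matrix(0, C, C, dimnames = list(rec$labels, rec$labels))
  lags <- matrix(0L, C, C, dimnames = list(rec$labels, rec$labels))
  for (i in seq_len(C)) {
    for (j in seq_len(C)) {
      if (i == j) next
      res <- tryCatch(
        lag_scan_te(rec$data[i, ], rec$data[j, ], te_cfg,
                    lag_min = lag_range[1], lag_max = lag_range[2]),
        error = function(e) {
          stop("pairwise TE failed for ", rec$labels[i], " -> ",
               rec$labels[j], ": ", conditionMessage(e))
        })
      te[i, j] <- res$value
      lags[i, j] <- res$delay_used
    }
  }
  structure(list(te = te, lags = lags, labels = rec$labels,
                 condition = rec$condition, subject = rec$subject_id,
                 rate = rec$rate),
            class = "te_matrices")
}

#' Convert a sample lag to milliseconds
#'
#' At the tenth-downsampled 100 Hz rate, lag 50 corresponds to 500 ms.
#'
#' @param lag lag in samples (>= 0).
#' @param rate_hz sampling rate in Hz.
#' @export
lag_to_ms <- function(lag, rate_hz) {
  if (any(lag < 0)) stop("lag must be non-negative")
  stopifnot(rate_hz > 0)
  lag * 1000 / rate_hz
}

#' Neutral-condition contrast of TE matrices
#'
#' Subtracts the voice-matched neutral setting's TE matrix from an odorized
#' setting's matrix (e.g. AM - NM), leaving the residual information flow
#' attributable to the odor manipulation. Negative residuals are retained;
#' thresholding later removes them.
#'
#' @param setting,neutral C x C TE matrices (or `te_matrices` objects) with
#'   identical channel labels, same subject.
#' @return C x C contrast matrix, diagonal 0.
#' @export
neutral_contrast <- function(setting, neutral) {
  a <- if (inherits(setting, "te_matrices")) setting$te else setting
  b <- if (inherits(neutral, "te_matrices")) neutral$te else neutral
  if (!identical(dim(a), dim(b)) || !identical(rownames(a), rownames(b))) {
    stop("setting and neutral matrices must share channel labels")
  }
  out <- a - b
  diag(out) <- 0
  out
}

#' Grand average of per-subject contrast matrices
#'
#' Element-wise mean over subjects, yielding one matrix per setting.
#'
#' @param contrasts non-empty list of congruent C x C matrices.
#' @return C x C mean matrix.
#' @export
grand_average <- function(contrasts) {
  if (!length(contrasts)) stop("no matrices to average")
  ref <- dimnames(contrasts[[1]])
  for (m in contrasts) {
    if (!identical(dimnames(m), ref)) stop("matrices must share labels")
  }
  Reduce(`+`, contrasts) / length(contrasts)
}

#' Bootstrap upper-CI thresholding of a grand-averaged TE matrix
#'
#' Resamples the pooled off-diagonal entries with replacement `B` times,
#' takes the mean of each resample, and uses the upper bound of the
#' `level`% CI of that bootstrap mean distribution (the 97.5th percentile at
#' the default level) as the threshold: entries strictly below it are zeroed,
#' equivalent to a one-tailed test keeping values greater than the average at
#' p < 0.025. Out-degrees (non-zero entries per source row) are counted on
#' the surviving matrix.
#'
#' @param mat C x C grand-averaged (contrast) TE matrix.
#' @param B bootstrap replicates (default 10,000).
#' @param level CI level in percent (default 95).
#' @param seed integer seed for the resampling stream.
#' @return list of class `thresholded_flow`: `contrast_mean`, `threshold`,
#'   `surviving`, `out_degree`, `labels`, plus the bootstrap settings.
#' @export
bootstrap_upper_threshold <- function(mat, B = 10000L, level = 95,
                                      seed = 1L) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat), B >= 100)
  C <- nrow(mat)
  off <- mat[row(mat) != col(mat)]
  if (length(off) < 2) stop("need at least 2 off-diagonal entries")
  upper_p <- 1 - (1 - level / 100) / 2
  thr <- withr_seed(seed, {
    boot_means <- vapply(seq_len(B), function(b)
      mean(off[sample.int(length(off), replace = TRUE)]), numeric(1))
    unname(quantile(boot_means, upper_p, type = 7))
  })
  surv <- mat
  surv[surv < thr] <- 0
  diag(surv) <- 0
  if (all(off == off[1])) {
    message("degenerate (all-equal) matrix: threshold equals the constant; ",
            "entries at the threshold survive")
  }
  deg <- rowSums(surv != 0)
  structure(list(contrast_mean = mat, threshold = thr, surviving = surv,
                 out_degree = deg, labels = rownames(mat),
                 B = B, level = level, seed = seed),
            class = "thresholded_flow")
}

#' Out-degree channel selection
#'
#' Bootstraps the mean of the out-degree vector and keeps the channels whose
#' out-degree strictly exceeds the upper bound of its `level`% CI, i.e. the
#' channels sending information to more targets than the average channel.
#' Channels at or below the bound are discarded; an all-zero degree vector
#' yields an empty (valid) selection.
#'
#' @param flow a [bootstrap_upper_threshold] result.
#' @param B bootstrap replicates (default 10,000).
#' @param level CI level in percent (default 95).
#' @param seed integer seed.
#' @return character vector of selected channel labels (possibly empty);
#'   attribute `"degree_bound"` holds the CI upper bound.
#' @export
select_channels <- function(flow, B = 10000L, level = 95, seed = 1L) {
  stopifnot(inherits(flow, "thresholded_flow"))
  deg <- flow$out_degree
  upper_p <- 1 - (1 - level / 100) / 2
  bound <- withr_seed(seed, {
    boot_means <- vapply(seq_len(B), function(b)
      mean(deg[sample.int(length(deg), replace = TRUE)]), numeric(1))
    unname(quantile(boot_means, upper_p, type = 7))
  })
  sel <- flow$labels[deg > bound]
  attr(sel, "degree_bound") <- bound
  sel
}

#' Cross-setting common channels
#'
#' Intersects the per-setting selections; settings with an empty selection
#' are dropped from the intersection and reported (mirroring the discard of
#' a setting with no surviving channels).
#'
#' @param selections named list of per-setting label vectors (>= 2 settings).
#' @return list: `common` (labels in every retained setting), `dropped`
#'   (settings with empty selections), `retained`.
#' @export
common_channels <- function(selections) {
  if (length(selections) < 2) stop("need selections from at least 2 settings")
  empty <- vapply(selections, function(s) length(s) == 0, logical(1))
  retained <- selections[!empty]
  common <- if (length(retained)) Reduce(intersect, retained) else character(0)
  list(common = common,
       dropped = names(selections)[empty],
       retained = names(selections)[!empty])
}
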