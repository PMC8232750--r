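#' Assemble the setting-labelled flow dataset
#'
#' One row per (setting, common channel): the channel's outgoing TE values to
#' all C channels form the feature vector; the setting supplies the class
#' label (1 = AF, 2 = AM, 3 = EM in the canonical three-setting analysis).
#' With 3 settings x 6 common channels x 62 targets this is an 18 x 62
#' design.
#'
#' @param setting_rows named list (one element per setting) of matrices with
#'   the common channels as rows (identical row sets) and all channels as
#'   columns; typically rows of each setting's thresholded grand-average
#'   matrix.
#' @return list of class `flow_dataset`: `X` (features), `y` (factor of
#'   setting labels), `channel` (source channel per row), `settings`.
#' @export
build_dataset <- function(setting_rows) {
  if (length(setting_rows) < 2) stop("need at least 2 settings (classes)")
  if (is.null(names(setting_rows)) || any(names(setting_rows) == "")) {
    stop("setting_rows must be a named list")
  }
  ref <- sort(rownames(setting_rows[[1]]))
  for (m in setting_rows) {
    if (!identical(sort(rownames(m)), ref)) {
      stop("all settings must share the same common-channel set")
    }
    if (ncol(m) != ncol(setting_rows[[1]])) stop("feature length mismatch")
  }
  X <- do.call(rbind, lapply(setting_rows, function(m) m[ref, , drop = FALSE]))
  y <- factor(rep(names(setting_rows), each = length(ref)),
              levels = names(setting_rows))
  structure(list(X = unname(X), y = y,
                 channel = rep(ref, times = length(setting_rows)),
                 settings = names(setting_rows),
                 feature_labels = colnames(setting_rows[[1]])),
            class = "flow_dataset")
}

# Standardize train columns; apply the train transform to test. Constant
# columns get unit scale so they standardize to zero rather than NaN.
standardize_pair <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

# Per-class softmax weights from a multinom fit: nnet parameterizes relative
# to the first class; recentring across classes gives one comparable
# coefficient vector per class.
softmax_weights <- function(fit) {
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  W <- rbind(0, cf[, -1, drop = FALSE]) # drop intercepts; first class = 0
  sweep(W, 2, colMeans(W))
}

#' Resampled hold-one-channel-per-class specificity protocol
#'
#' Per run, one channel per setting is held out; a multinomial (softmax)
#' logistic regression with L2 regularization (decay 1.0) is fit on the
#' remaining rows after train-only feature standardization, and accuracy,
#' macro-averaged precision, recall and F1 are scored on the held-out rows
#' (15 x 62 train, 3 x 62 test in the canonical design). Aggregates over
#' `runs` repetitions; chance level is 100/k % for k balanced classes.
#'
#' @param ds a [build_dataset] result (balanced classes).
#' @param runs number of resampled runs (default 1,000).
#' @param seed integer seed for the hold-out stream.
#' @param decay L2 penalty passed to [nnet::multinom] (default 1.0).
#' @param shuffle_labels permute the class labels independently in every run
#'   (permutation-test style null calibration; the mean accuracy then
#'   concentrates at the chance level).
#' @return list of class `specificity_report`: `accuracy_mean/sd` (%),
#'   `precision_*`, `recall_*`, `f1_*`, `confusion` (k x k counts over all
#'   test rows), `weights` (per-setting mean coefficient vectors),
#'   `accuracies` (per run, %), `chance_level`, `train_dim`, `test_dim`.
#' @export
run_protocol <- function(ds, runs = 1000L, seed = 1L, decay = 1.0,
                         shuffle_labels = FALSE) {
  stopifnot(inherits(ds, "flow_dataset"), runs >= 1)
  k <- nlevels(ds$y)
  per_class <- table(ds$y)
  if (length(unique(per_class)) != 1) stop("dataset must be balanced")
  if (all(apply(ds$X, 2, sd) == 0)) stop("all features constant")

  withr_seed(seed, {
    y0 <- ds$y
    acc <- prec <- rec <- f1 <- numeric(runs)
    confusion <- matrix(0L, k, k, dimnames = list(true = levels(y0),
                                                  predicted = levels(y0)))
    wsum <- matrix(0, k, ncol(ds$X))
    train_dim <- test_dim <- NULL
    for (r in seq_len(runs)) {
      y <- if (shuffle_labels) sample(y0) else y0
      idx_by_class <- split(seq_along(y), y)
      test_idx <- vapply(idx_by_class, function(ix) ix[sample.int(length(ix), 1)],
                         integer(1))
      train_idx <- setdiff(seq_along(y), test_idx)
      std <- standardize_pair(ds$X[train_idx, , drop = FALSE],
                              ds$X[test_idx, , drop = FALSE])
      train_dim <- dim(std$train); test_dim <- dim(std$test)
      df_train <- data.frame(std$train)
      df_train$.y <- droplevels(y[train_idx])
      fit <- nnet::multinom(.y ~ ., data = df_train, decay = decay,
                            trace = FALSE, maxit = 200, MaxNWts = 10000)
      pred <- predict(fit, newdata = data.frame(std$test))
      truth <- y[test_idx]
      cm <- table(factor(truth, levels(y)), factor(pred, levels(y)))
      confusion <- confusion + cm
      acc[r] <- 100 * mean(pred == truth)
      pr <- diag(cm) / pmax(colSums(cm), 1) # undefined precision -> 0
      rc <- diag(cm) / pmax(rowSums(cm), 1)
      f <- ifelse(pr + rc == 0, 0, 2 * pr * rc / (pr + rc))
      prec[r] <- mean(pr); rec[r] <- mean(rc); f1[r] <- mean(f)
      wsum <- wsum + softmax_weights(fit)
    }
    weights <- wsum / runs
    rownames(weights) <- levels(y0)
    colnames(weights) <- ds$feature_labels
    structure(list(
      accuracy_mean = mean(acc), accuracy_sd = sd(acc),
      precision_mean = mean(prec), precision_sd = sd(prec),
      recall_mean = mean(rec), recall_sd = sd(rec),
      f1_mean = mean(f1), f1_sd = sd(f1),
      confusion = confusion, weights = weights, accuracies = acc,
      chance_level = 100 / k, runs = runs, seed = seed, decay = decay,
      train_dim = train_dim, test_dim = test_dim,
      shuffled = shuffle_labels,
      notes = paste("features standardized on train only; L2 decay fixed;",
                    "weights averaged over runs")),
      class = "specificity_report")
  })
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("Specificity over %d runs (chance %.2f%%)\n", x$runs,
              x$chance_level))
  cat(sprintf("  accuracy  M = %.2f%%  SD = %.2f\n", x$accuracy_mean,
              x$accuracy_sd))
  cat(sprintf("  precision M = %.2f  SD = %.2f\n", x$precision_mean,
              x$precision_sd))
  cat(sprintf("  recall    M = %.2f  SD = %.2f\n", x$recall_mean, x$recall_sd))
  cat(sprintf("  F1        M = %.2f  SD = %.2f\n", x$f1_mean, x$f1_sd))
  invisible(x)
}

#' Signed-rank test of accuracy against chance
#'
#' Wilcoxon signed-rank test of the per-run accuracies against the chance
#' level, with Rosenthal effect size `W / sqrt(runs)`.
#'
#' @param report a [run_protocol] result (per-run accuracies retained).
#' @return `group_test_result`, or a zero-evidence stub when every run sits
#'   exactly at chance.
#' @export
test_above_chance <- function(report) {
  stopifnot(inherits(report, "specificity_report"))
  d <- report$accuracies - report$chance_level
  if (all(d == 0)) {
    return(group_test_result("signed_rank", 0, report$runs - 1L, 1, 0,
                             extra = list(note = "no evidence: all runs at chance")))
  }
  wilcoxon_r(report$accuracies, mode = "signed_rank",
             mu = report$chance_level)
}

#' Compare per-setting weight maps
#'
#' Kruskal-Wallis across the settings' coefficient vectors (N = k x C),
#' followed by pairwise rank-sum tests with effect sizes.
#'
#' @param weights matrix (settings x channels) or named list of equal-length
#'   vectors.
#' @return list: `kruskal` (`group_test_result`), `pairwise` (named list of
#'   `group_test_result`).
#' @export
compare_weights <- function(weights) {
  if (is.matrix(weights)) {
    weights <- stats::setNames(
      lapply(seq_len(nrow(weights)), function(i) weights[i, ]),
      rownames(weights))
  }
  if (length(unique(lengths(weights))) != 1) stop("weight length mismatch")
  kw <- kruskal_wallis_r(weights)
  pairs <- utils::combn(names(weights), 2, simplify = FALSE)
  pw <- lapply(pairs, function(p) wilcoxon_r(weights[[p[1]]], weights[[p[2]]],
                                             mode = "ranksum"))
  names(pw) <- vapply(pairs, paste, character(1), collapse = " vs ")
  list(kruskal = kw, pairwise = pw)
}
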