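#' Construct a multichannel recording
#'
#' Container for one subject x condition recording: a channels x samples
#' matrix in nominal microvolts with ordered channel labels and the sampling
#' rate in Hz.
#'
#' @param data channels x samples numeric matrix (µV).
#' @param labels character vector of channel names, one per row.
#' @param rate sampling rate in Hz (> 0).
#' @param subject_id subject identifier.
#' @param condition one of [CONDITIONS] or `"baseline"`.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, labels, rate, subject_id = NA_character_,
                          condition = "baseline") {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data))) {
    stop("recording data must be a finite numeric matrix")
  }
  if (length(labels) != nrow(data)) {
    stop("labels length (", length(labels), ") must equal channel count (",
         nrow(data), ")")
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0")
  if (!condition %in% c(CONDITIONS, "baseline")) {
    stop("unknown condition: ", condition)
  }
  rownames(data) <- labels
  structure(
    list(data = data, labels = as.character(labels), rate = rate,
         subject_id = subject_id, condition = condition),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat(sprintf("  subject: %s  condition: %s\n", x$subject_id, x$condition))
  cat("  channels:", paste(head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "...", "\n")
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `eeg_recording`.
#' @export
n_samples <- function(rec) ncol(rec$data)
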