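#' Signal-conditioning configuration
#'
#' Defaults reproduce the conditioning applied before transfer-entropy
#' estimation: 0.5--50 Hz zero-phase band-pass at a 24 dB/octave slope,
#' 125 µV amplitude artifact rejection on 1-s segments, tenth-length
#' downsampling with anti-alias filtering, and per-channel linear detrending.
#'
#' @param band numeric pair, band edges in Hz.
#' @param order Butterworth order (4 ~ 24 dB/octave asymptotic slope).
#' @param artifact_threshold amplitude threshold in µV.
#' @param segment_s artifact segment length in seconds.
#' @param downsample_factor decimation factor.
#' @param antialias apply a low-pass before decimation (`FALSE` gives naive
#'   subsampling, kept for sensitivity checks).
#' @export
preprocess_config <- function(band = c(0.5, 50), order = 4L,
                              artifact_threshold = 125,
                              segment_s = 1,
                              downsample_factor = 10L,
                              antialias = TRUE) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2],
            artifact_threshold > 0, downsample_factor >= 1)
  structure(list(band = band, order = as.integer(order),
                 artifact_threshold = artifact_threshold,
                 segment_s = segment_s,
                 downsample_factor = as.integer(downsample_factor),
                 antialias = antialias),
            class = "preprocess_config")
}

# Zero-phase (forward-backward) Butterworth filtering of one channel.
filtfilt_safe <- function(flt, x) {
  as.numeric(signal::filtfilt(flt, x))
}

#' Zero-phase band-pass filter
#'
#' High-pass then low-pass Butterworth sections (applied separately for
#' numerical stability at a low normalized high-pass edge), each run
#' forward-backward so no phase distortion biases downstream lag estimates.
#' Removes the DC component; preserves length.
#'
#' @param rec an [eeg_recording].
#' @param cfg a [preprocess_config].
#' @return filtered [eeg_recording].
#' @export
bandpass <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate / 2
  if (cfg$band[2] >= nyq) {
    stop("band edge ", cfg$band[2], " Hz invalid for rate ", rec$rate, " Hz")
  }
  hp <- signal::butter(cfg$order, cfg$band[1] / nyq, type = "high")
  lp <- signal::butter(cfg$order, cfg$band[2] / nyq, type = "low")
  out <- t(apply(rec$data, 1, function(ch) {
    filtfilt_safe(lp, filtfilt_safe(hp, ch - mean(ch)))
  }))
  eeg_recording(out, rec$labels, rec$rate, rec$subject_id, rec$condition)
}

#' Amplitude-based artifact rejection
#'
#' Flags every contiguous segment (default 1 s) in which any channel exceeds
#' the amplitude threshold (default 125 µV) and excises flagged segments from
#' all channels jointly, preserving time-locked integrity across channels.
#'
#' @param rec an [eeg_recording].
#' @param cfg a [preprocess_config].
#' @return list: `recording` (cleaned), `mask` (logical, `TRUE` for flagged,
#'   one entry per segment), `segment_samples`.
#' @export
reject_artifacts <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  seg_len <- max(1L, as.integer(round(cfg$segment_s * rec$rate)))
  n <- n_samples(rec)
  n_seg <- ceiling(n / seg_len)
  seg_of <- rep(seq_len(n_seg), each = seg_len)[seq_len(n)]
  peak <- apply(abs(rec$data), 2, max)
  mask <- as.vector(tapply(peak, factor(seg_of, levels = seq_len(n_seg)),
                           function(p) any(p > cfg$artifact_threshold)))
  if (mean(mask) > 0.5) {
    warning(sprintf("artifact rejection flagged %.0f%% of the data",
                    100 * mean(mask)))
  }
  keep <- !mask[seg_of]
  out <- rec$data[, keep, drop = FALSE]
  list(
    recording = eeg_recording(out, rec$labels, rec$rate,
                              rec$subject_id, rec$condition),
    mask = mask,
    segment_samples = seg_len
  )
}

#' Tenth-length downsampling
#'
#' Anti-alias low-pass (Butterworth at 80% of the new Nyquist, zero-phase)
#' then decimation keeping every `factor`-th sample, so a 120,000-sample
#' recording becomes 12,000 points and the rate drops tenfold.
#'
#' @param rec an [eeg_recording].
#' @param factor decimation factor (default 10).
#' @param antialias low-pass before decimating (default `TRUE`).
#' @return decimated [eeg_recording]; new length `floor(old / factor)`,
#'   new rate `rate / factor`.
#' @export
downsample_tenth <- function(rec, factor = 10L, antialias = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1L) return(rec)
  if (n_samples(rec) < factor) stop("recording shorter than one factor")
  dat <- rec$data
  if (antialias) {
    lp <- signal::butter(4, 0.8 / factor, type = "low")
    dat <- t(apply(dat, 1, function(ch) filtfilt_safe(lp, ch)))
  }
  keep <- seq.int(factor, ncol(dat), by = factor)
  eeg_recording(dat[, keep, drop = FALSE], rec$labels, rec$rate / factor,
                rec$subject_id, rec$condition)
}

#' Per-channel linear detrending
#'
#' Removes the least-squares line from every channel, leaving zero mean and
#' zero linear trend.
#'
#' @param rec an [eeg_recording].
#' @return detrended [eeg_recording].
#' @export
detrend_linear <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- n_samples(rec)
  if (n < 2) stop("need at least 2 samples to detrend")
  X <- cbind(1, seq_len(n))
  # One QR for all channels: residuals of data' ~ [1, t].
  res <- t(qr.resid(qr(X), t(rec$data)))
  eeg_recording(res, rec$labels, rec$rate, rec$subject_id, rec$condition)
}

#' Full conditioning pipeline
#'
#' Filter -> artifact rejection -> downsample -> detrend, in that order.
#'
#' @param rec an [eeg_recording].
#' @param cfg a [preprocess_config].
#' @return list: `recording` (conditioned), `artifact_mask`.
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  filtered <- bandpass(rec, cfg)
  rej <- reject_artifacts(filtered, cfg)
  down <- downsample_tenth(rej$recording, cfg$downsample_factor,
                           antialias = cfg$antialias)
  list(recording = detrend_linear(down), artifact_mask = rej$mask)
}
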