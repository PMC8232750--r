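#' Standard 10-10 montage channel labels
#'
#' Returns the first `n` labels of a 64-electrode active-cap roster laid out
#' per the international 10-10 system, with the recording reference (FCz) and
#' the ground (Fpz) excluded first, so the default `n = 62` reproduces a
#' 62-channel analysis montage. Labels include the frontal, central, parietal
#' and parieto-occipital sites (F3, F2, C2, P5, P6, PO3, ...) used throughout
#' the pipeline.
#'
#' @param n number of channels (1--62).
#' @return character vector of unique channel labels.
#' @export
montage_1010 <- function(n = 62) {
  roster <- c(
    "Fp1", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8", "FT10",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz"
  )
  stopifnot(!anyDuplicated(roster))
  if (n < 1 || n > length(roster)) {
    stop("n must be between 1 and ", length(roster))
  }
  roster[seq_len(n)]
}
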