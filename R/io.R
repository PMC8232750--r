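#' Write a recording as delimited text plus JSON sidecar
#'
#' Canonical diff-able fixture format: a channels x samples tab-separated
#' matrix (`<basename>.tsv`) and a JSON sidecar (`<basename>.json`) holding
#' labels, rate, subject and condition.
#'
#' @param rec an [eeg_recording].
#' @param basename path without extension.
#' @return `basename`, invisibly.
#' @export
write_recording <- function(rec, basename) {
  stopifnot(inherits(rec, "eeg_recording"))
  write.table(format(rec$data, digits = 17, trim = TRUE, scientific = TRUE),
              paste0(basename, ".tsv"),
              sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  jsonlite::write_json(
    list(labels = rec$labels, rate = rec$rate, subject = rec$subject_id,
         condition = rec$condition),
    paste0(basename, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(basename)
}

#' Read a recording written by [write_recording] or a BrainVision triple
#'
#' Dispatches on the path: `<basename>.vhdr` reads a BrainVision Core triple;
#' otherwise `<basename>.tsv` + `<basename>.json` are expected.
#'
#' @param basename path without extension, or a `.vhdr` path.
#' @return an [eeg_recording].
#' @export
read_recording <- function(basename) {
  if (grepl("\\.vhdr$", basename)) return(read_brainvision(basename))
  tsv <- paste0(basename, ".tsv"); side <- paste0(basename, ".json")
  if (!file.exists(tsv)) stop("missing data matrix: ", tsv)
  if (!file.exists(side)) stop("missing JSON sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  dat <- as.matrix(read.table(tsv, sep = "\t", header = FALSE))
  dimnames(dat) <- NULL
  eeg_recording(dat, meta$labels, meta$rate,
                subject_id = meta$subject %||% NA_character_,
                condition = meta$condition %||% "baseline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a BrainVision Core triple
#'
#' Minimal writer for the `.vhdr`/`.vmrk`/`.eeg` triple: INI-style header,
#' one new-segment marker, and multiplexed IEEE float32 little-endian binary
#' data in microvolts. Intended for interoperability round-trips; the
#' delimited format is the canonical fixture format.
#'
#' @param rec an [eeg_recording].
#' @param basename path without extension.
#' @return `basename`, invisibly.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "eeg_recording"))
  stem <- basename(basename)
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$rate, scientific = FALSE)),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)), rec$labels)
  )
  writeLines(hdr, paste0(basename, ".vhdr"))
  writeLines(c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0"
  ), paste0(basename, ".vmrk"))
  con <- file(paste0(basename, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(basename)
}

#' Read a BrainVision Core triple
#'
#' Supports the subset written by [write_brainvision] (multiplexed
#' IEEE_FLOAT_32 or INT_16 with per-channel resolution).
#'
#' @param vhdr path to the `.vhdr` header.
#' @param subject_id,condition metadata not carried by the format.
#' @return an [eeg_recording].
#' @export
read_brainvision <- function(vhdr, subject_id = NA_character_,
                             condition = "baseline") {
  if (!file.exists(vhdr)) stop("missing header: ", vhdr)
  lines <- readLines(vhdr, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) {
      stop("malformed header ", vhdr, ": missing '", key, "' entry")
    }
    sub(paste0("^", key, "="), "", hit[1])
  }
  n_chan <- as.integer(get_field("NumberOfChannels"))
  rate <- 1e6 / as.numeric(get_field("SamplingInterval"))
  fmt <- get_field("BinaryFormat")
  orient <- get_field("DataOrientation")
  if (orient != "MULTIPLEXED") stop("unsupported DataOrientation: ", orient)
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) != n_chan) {
    stop("malformed header ", vhdr, ": ", length(ch_lines),
         " channel entries for NumberOfChannels=", n_chan)
  }
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(parts, `[`, character(1), 1)
  resolution <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, numeric(1))
  eeg_path <- file.path(dirname(vhdr), get_field("DataFile"))
  if (!file.exists(eeg_path)) stop("missing data file: ", eeg_path)
  sz <- file.size(eeg_path)
  if (fmt == "IEEE_FLOAT_32") {
    raw_vals <- readBin(eeg_path, numeric(), n = sz / 4, size = 4,
                        endian = "little")
  } else if (fmt == "INT_16") {
    raw_vals <- readBin(eeg_path, integer(), n = sz / 2, size = 2,
                        signed = TRUE, endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  n_samp <- length(raw_vals) %/% n_chan
  dat <- matrix(raw_vals[seq_len(n_chan * n_samp)], nrow = n_chan) *
    resolution
  eeg_recording(dat, labels, rate, subject_id, condition)
}
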