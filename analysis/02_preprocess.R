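#!/usr/bin/env Rscript
# Stage 2 — signal conditioning.
#
# Applies the conditioning chain (0.5-50 Hz zero-phase band-pass, 125 uV
# artifact rejection on 1-s segments, tenth-length downsampling, linear
# detrending) to the full-rate recording from stage 1 and reports what
# each stage did.

suppressPackageStartupMessages(library(teflow))

rec <- read_recording("results/fullrate_recording_S1_EM")
cat("Input:", nrow(rec$data), "x", ncol(rec$data), "@", rec$rate, "Hz\n")

out <- preprocess(rec)
cat(sprintf("Artifact segments flagged: %d of %d (%.1f%%)\n",
            sum(out$artifact_mask), length(out$artifact_mask),
            100 * mean(out$artifact_mask)))
cat("Conditioned:", nrow(out$recording$data), "x", ncol(out$recording$data),
    "@", out$recording$rate, "Hz\n")

write_recording(out$recording, "results/conditioned_S1_EM")
summary_df <- data.frame(
  stage = c("input_samples", "flagged_segments", "output_samples",
            "output_rate_hz"),
  value = c(ncol(rec$data), sum(out$artifact_mask),
            ncol(out$recording$data), out$recording$rate))
write.csv(summary_df, "results/preprocess_summary.csv", row.names = FALSE)
cat("Wrote results/conditioned_S1_EM.{tsv,json} and preprocess_summary.csv\n")
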