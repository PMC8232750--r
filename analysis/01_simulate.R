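#!/usr/bin/env Rscript
# Stage 1 — simulate the validation study.
#
# Generates the reference ground-truth study (8 channels at 100 Hz, 6
# subjects; F3 and C2 drive three targets each in the odorized settings;
# EF is an exact re-labeling of NF) plus one full-rate (1,000 Hz) recording
# with injected artifacts for the conditioning stage, and writes a sample
# fixture pair plus the ground-truth edge list.

suppressPackageStartupMessages(library(teflow))
dir.create("results", showWarnings = FALSE)

design <- scaled_study_design(seed = 42)
cat("Design:", design$n_channels, "channels,", design$n_subjects,
    "subjects,", design$duration_samples, "samples @", design$rate, "Hz\n")

truth <- ground_truth_graph(design, "EM")
write.csv(truth, "results/ground_truth_EM.csv", row.names = FALSE)
cat("Ground truth (EM):", nrow(truth), "directed couplings from",
    paste(unique(truth$source), collapse = " and "), "\n")

rec <- generate_recording(design, "S1", "EM")
write_recording(rec, "results/example_recording_S1_EM")
cat("Wrote results/example_recording_S1_EM.{tsv,json} —",
    nrow(rec$data), "x", ncol(rec$data), "\n")

# Full-rate recording with artifacts, for stage 2
full <- synth_design(n_channels = 4, channel_labels = montage_1010(4),
                     rate = 1000, duration_samples = 30000, ar_coeff = 0.5,
                     noise_sd = 10, n_subjects = 1, seed = 42,
                     inject_artifacts = TRUE)
rec_full <- generate_recording(full, "S1", "EM")
write_recording(rec_full, "results/fullrate_recording_S1_EM")
cat("Full-rate recording:", nrow(rec_full$data), "x", ncol(rec_full$data),
    sprintf("; %.2f%% of samples exceed 100 uV\n",
            100 * mean(abs(rec_full$data) > 100)))
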