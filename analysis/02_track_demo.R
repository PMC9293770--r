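#!/usr/bin/env Rscript
# Step 2 -- verify the imaging arm of the pipeline on synthetic movies.
#
# Renders one simulated bead trajectory as a multi-frame TIFF (Gaussian
# spot, 27.6 nm/pixel, 20 frames/s), recovers the track by sub-pixel
# centroid localization, and compares it with the known ground truth.
# This stands in for the DIC recordings: real analyses start from either
# image stacks (track_stack) or already-tracked position tables.

suppressPackageStartupMessages(library(phagomotion))

cfg <- sim_config(duration = 30, seed = 321L)
tr <- simulate_trajectory(cfg)
set.seed(321L)
stack <- render_image_stack(tr)

dir.create("scratch", showWarnings = FALSE)
write_stack(stack, "scratch/demo_bead.tif")
stack2 <- read_stack("scratch/demo_bead.tif")

origin <- attr(stack2, "origin_nm")
start_px <- c((tr$x_true_nm[1] - origin[["x"]]) / cfg$pixel_size,
              (tr$y_true_nm[1] - origin[["y"]]) / cfg$pixel_size)
tracked <- track_stack(stack2, start_px, tracking_config())

rms_true <- sqrt(mean((tracked$x_nm - tr$x_true_nm)^2 +
                        (tracked$y_nm - tr$y_true_nm)^2))
rms_obs <- sqrt(mean((tracked$x_nm - tr$x_nm)^2 +
                       (tracked$y_nm - tr$y_nm)^2))

dir.create("results", showWarnings = FALSE)
write.table(
  data.frame(n_frames = nrow(tracked),
             rms_vs_truth_nm = rms_true,
             rms_vs_noisy_observation_nm = rms_obs,
             pixel_size_nm = cfg$pixel_size,
             frame_rate = cfg$frame_rate),
  "results/02_tracking_accuracy.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

message(sprintf(
  "tracked %d/%d frames; RMS vs true positions %.1f nm (vs the 9.8 nm noise floor)",
  nrow(tracked), nrow(tr), rms_true))
message("summary in results/02_tracking_accuracy.tsv")
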