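#!/usr/bin/env Rscript

# 01 — Simulate a study-like imaging session.
#
# Generates a synthetic ganglion-cell-layer field (160 x 215 um at 1 um/px),
# renders a 0.2 Hz square-wave stimulation video with indicator kinetics,
# eye-motion jitter and shot-like noise, and writes the video plus its
# generative ground truth under results/data/. Run from the repository root.

suppressPackageStartupMessages(library(facile))

out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

stim <- stimulus_spec(frequency = 0.2, waveform = "square")
field <- field_spec(width_px = 215, height_px = 160, n_cells = 30)

truth <- generate_cell_field(field, polarity_mix = c(0.5, 0.3, 0.2),
                             amplitude_range = c(0.1, 0.5), seed = 101)
video <- render_video(truth, stim, indicator_kinetics(), n_frames = 1250,
                      frame_rate = 25, noise_sd = 2,
                      motion = motion_spec(jitter_sd = 1, max_excursion = 4),
                      seed = 102)

write_stack(video$session, file.path(out_dir, "session1.tif"))
write_mask(roi_mask(video$truth$label_mask),
           file.path(out_dir, "session1_truth_mask.tif"))
write_ground_truth(video$truth, file.path(out_dir, "session1_truth.json"))

n_resp <- sum(truth$cells$polarity != "NONE")
cat(sprintf("simulated %d cells (%d responsive: %d ON, %d OFF) over %d frames\n",
            nrow(truth$cells), n_resp,
            sum(truth$cells$polarity == "ON"),
            sum(truth$cells$polarity == "OFF"), 1250))
cat(sprintf("wrote video, truth mask and ground truth to %s\n", out_dir))
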