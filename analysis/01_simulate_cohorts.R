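#!/usr/bin/env Rscript
# Step 1 -- simulate the two bead-phagosome cohorts.
#
# Control macrophages: default motor-switching parameters (mean dwell 6 s
# in each state, per-run speeds 50-1500 nm/s around 500 nm/s, D = 1e4
# nm^2/s when diffusive, 9.8 nm localization noise floor, 20 frames/s,
# 150 s per bead). Treated cells emulate impaired motor engagement
# (NHE9-overexpression-like phenotype): 3x higher k_off, 2x lower k_on.
# 63 beads per group, matching the early-phagosome tracking scale.
#
# Raw trajectories (large) go to scratch/cohorts/; the ground-truth group
# summary (small) goes to results/.

suppressPackageStartupMessages(library(phagomotion))

cfg_control <- sim_config(seed = 20260920L)
cfg_treated <- sim_config(k_off = 0.5, k_on = 1 / 12, seed = 20260921L)

message("simulating 63 + 63 beads ...")
cohort <- simulate_cohort(cfg_control, cfg_treated, n_per_group = 63)

for (grp in c("control", "treated")) {
  d <- file.path("scratch", "cohorts", grp)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  trs <- cohort[[grp]]
  for (i in seq_along(trs)) {
    write_trajectory(trs[[i]], file.path(d, sprintf("bead_%02d.tsv", i)))
  }
  write_config(if (grp == "control") cfg_control else cfg_treated,
               file.path(d, "sim_config.txt"))
}

dir.create("results", showWarnings = FALSE)
write.table(cohort$truth, "results/01_truth_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("ground truth per group:")
print(cohort$truth, row.names = FALSE)
message("trajectories written under scratch/cohorts/, ",
        "truth table in results/01_truth_summary.tsv")
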