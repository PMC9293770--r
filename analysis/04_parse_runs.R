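#!/usr/bin/env Rscript
# Step 4 -- parse directed motion into constant-velocity runs.
#
# Consecutive directed segments (diffusive gaps <= 0.25 s bridged) form
# long directed tracks; each is segmented into constant-velocity pieces by
# penalized change-point detection and the pieces are scored against the
# run criteria (net displacement > 200 nm, speed > 50 nm/s, duration >=
# 0.25 s; slower pieces are pauses). Requires step 03.

suppressPackageStartupMessages(library(phagomotion))

res <- tryCatch(readRDS("scratch/analysis_two_groups.rds"),
                error = function(e) stop("run analysis/03_segment_motion.R first",
                                         call. = FALSE))

dir.create("results", showWarnings = FALSE)
summ <- do.call(rbind, lapply(c("control", "treated"), function(grp) {
  runs <- res[[grp]]$runs
  by_kind <- table(factor(runs$kind, c("run", "pause", "subthreshold")))
  r <- runs[runs$kind == "run", ]
  data.frame(group = grp,
             n_pieces = nrow(runs),
             n_runs = by_kind[["run"]],
             n_pauses = by_kind[["pause"]],
             n_subthreshold = by_kind[["subthreshold"]],
             mean_run_length_nm = mean(r$net_nm),
             mean_run_speed_nm_s = mean(r$speed_nm_s),
             mean_run_duration_s = mean(r$duration_s))
}))
write.table(summ, "results/04_runs_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# full classified piece tables are a few thousand rows; keep them in scratch
for (grp in c("control", "treated")) {
  write.table(res[[grp]]$runs, sprintf("scratch/04_pieces_%s.tsv", grp),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

print(summ, row.names = FALSE)
message("wrote results/04_runs_summary.tsv (full piece tables in scratch/)")
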