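#!/usr/bin/env Rscript
# Step 5 -- transport statistics and group comparison.
#
# Per-bead percent directed/diffusive motion, run length and velocity over
# runs, dissociation rate (run terminations per unit motor-bound time) per
# bead; mean +/- SEM per group and Welch two-sample t-tests between
# conditions with the *, **, ***, **** star convention. Requires step 03.

suppressPackageStartupMessages(library(phagomotion))

res <- tryCatch(readRDS("scratch/analysis_two_groups.rds"),
                error = function(e) stop("run analysis/03_segment_motion.R first",
                                         call. = FALSE))

dir.create("results", showWarnings = FALSE)
rows <- do.call(rbind, lapply(c("control", "treated"), function(grp) {
  s <- res[[grp]]$summary
  data.frame(group = grp, n_beads = s$n_beads, n_runs = s$n_runs,
             pct_directed = s$pct_directed$mean,
             pct_directed_sem = s$pct_directed$sem,
             pct_diffusive = s$pct_diffusive$mean,
             pct_diffusive_sem = s$pct_diffusive$sem,
             run_length_nm = s$run_length$mean,
             run_length_sem = s$run_length$sem,
             velocity_nm_s = s$velocity$mean,
             velocity_sem = s$velocity$sem,
             dissociation_rate_s = s$dissociation$mean,
             dissociation_rate_sem = s$dissociation$sem)
}))
write.table(rows, "results/05_transport_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$comparisons, "results/05_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(res$control$summary)
print(res$treated$summary)
message("group comparison (Welch two-sample t-tests):")
print(res$comparisons, row.names = FALSE)
message("wrote results/05_transport_summary.tsv and 05_comparisons.tsv")
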