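#!/usr/bin/env Rscript
# Fit the four diffusion models voxelwise to every subject of the simulated
# cohort (direction-averaged signals, bounded Levenberg-Marquardt) and
# extract the VOI mean of each of the nine parameters, producing the
# per-subject cohort table all downstream statistics consume.

suppressPackageStartupMessages(library(gliodwi))

SEED <- 20260929  # must match 01_simulate_cohort.R
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_cohort_config(paper_cohort_groups(), snr = 50, seed = SEED)
cohort <- generate_cohort(cfg)

t0 <- Sys.time()
fitted <- run_cohort_pipeline(cohort)
cat(sprintf("Fitted 4 models x %d voxels in %.1f s.\n",
            sum(cohort$labels$n_voxels),
            as.numeric(difftime(Sys.time(), t0, units = "secs"))))

write_cohort_table(fitted, "results/cohort_fitted.csv")

# recovery of the generating truth at the subject level
for (p in c("CTRW_alpha", "Mono_ADC")) {
  err <- fitted[[p]] - cohort$truth[[p]]
  cat(sprintf("%s: mean fitted-minus-truth %+0.4f (sd %.4f)\n",
              p, mean(err), sd(err)))
}
cat("Note: the Rician noise floor inflates fitted CTRW_alpha slightly, and\n")
cat("more so in the wild-type group (lower alpha, faster high-b decay).\n")
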