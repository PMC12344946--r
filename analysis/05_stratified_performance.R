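#!/usr/bin/env Rscript
# Re-evaluate the IDH decision rule for CTRW_alpha inside morphology strata
# (enhancement, cystic/necrosis, edema) at the FIXED whole-cohort Youden
# threshold — the cut-off is not re-optimized per stratum — and quantify
# inter-observer-style agreement of the VOI means with ICC(2,1), emulating a
# second delineation by re-extracting each VOI mean from a random subset of
# its voxels.

suppressPackageStartupMessages(library(gliodwi))

SEED <- 20260929
fitted <- read_cohort_table("results/cohort_fitted.csv")
roc_idh <- read.csv("results/roc_idh.csv")

thr <- roc_idh$threshold[roc_idh$parameter == "CTRW_alpha"]
dirn <- roc_idh$direction[roc_idh$parameter == "CTRW_alpha"]

strat <- do.call(rbind, lapply(
  c("enhancement", "cystic_necrosis", "edema"),
  function(flag) stratified_performance(fitted, flag, "CTRW_alpha",
                                        threshold = thr, direction = dirn,
                                        question = "IDH")))
write.csv(strat, "results/stratified_performance.csv", row.names = FALSE)
cat("CTRW_alpha at the fixed whole-cohort threshold", round(thr, 3), ":\n")
print(as.data.frame(strat), row.names = FALSE)

# ICC(2,1): two "raters" = VOI means over two random 80% voxel subsets of a
# refitted 20-subject subsample
set.seed(SEED)
gs <- paper_cohort_groups()
gs[[1]]$n_subjects <- 10L; gs[[2]]$n_subjects <- 4L; gs[[3]]$n_subjects <- 6L
coh <- generate_cohort(synthetic_cohort_config(gs, snr = 50, seed = SEED))
ratings <- t(vapply(coh$subjects, function(s) {
  sig <- s$signals$avg
  n <- nrow(sig)
  vapply(1:2, function(r) {
    pick <- sample(n, max(3, round(0.8 * n)))
    mean(vapply(pick, function(v) {
      fit_ctrw(dwi_signal(coh$scheme, sig[v, ]))$params[["alpha"]]
    }, 0))
  }, 0)
}, numeric(2)))
icc <- icc_two_way_random(ratings)
cat(sprintf("\nICC(2,1) of CTRW_alpha between delineation variants: %.3f (95%% CI %.3f-%.3f)\n",
            icc$icc, icc$ci_lo, icc$ci_hi))
write.csv(data.frame(parameter = "CTRW_alpha", icc = icc$icc,
                     ci_lo = icc$ci_lo, ci_hi = icc$ci_hi,
                     model = icc$model),
          "results/interrater_icc.csv", row.names = FALSE)
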