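#!/usr/bin/env Rscript
# Group comparisons on the fitted cohort table: for each of the nine
# parameters and both genotype questions (IDH wild-type vs mutant; 1p/19q
# non-codeleted vs codeleted within mutants), the Shapiro-Wilk/Levene-gated
# t / Welch / Mann-Whitney test, Cohen's d, and Benjamini-Hochberg
# adjustment over the 18 hypotheses jointly.

suppressPackageStartupMessages(library(gliodwi))

fitted <- read_cohort_table("results/cohort_fitted.csv")
stats_tab <- genotype_comparison_table(fitted)
write.csv(stats_tab, "results/group_statistics.csv", row.names = FALSE)

sig <- stats_tab[stats_tab$p_bh < 0.05, ]
cat("Significant after BH (p_bh < 0.05):\n")
print(as.data.frame(sig[, c("question", "parameter", "test", "p_raw",
                            "p_bh", "cohens_d")]), row.names = FALSE)
cat("\nLargest |d| per question:\n")
for (q in unique(stats_tab$question)) {
  s <- stats_tab[stats_tab$question == q, ]
  top <- s[which.max(abs(s$cohens_d)), ]
  cat(sprintf("  %s: %s (d = %.3f)\n", q, top$parameter, top$cohens_d))
}
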