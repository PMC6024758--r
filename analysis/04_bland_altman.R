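#!/usr/bin/env Rscript
# Step 4: ratio-scale Bland-Altman agreement and ground-truth recovery.
#
# Reports the geometric-mean PrUIE/mUIE ratio and antilogged 95% limits of
# agreement per equation (per-pair exports were written in step 3), draws
# the three panels, and closes the loop against the simulator's hidden
# truth: estimated vs true below-EAR prevalence and the spot-vs-24h rank
# correlation.

suppressPackageStartupMessages(library(iodstatus))

cohort <- read_cohort("results/cohort.csv")
truth <- read.csv("results/cohort_truth.csv")
full <- merge(cohort, truth, by = "id", sort = FALSE)

report <- run_pipeline(cohort)
cat("log-scale Bland-Altman agreement (PrUIE/mUIE):\n")
for (eq in names(report$equations)) {
  ba <- report$equations[[eq]]$bland_altman
  cat(sprintf("  %-8s mean ratio %.0f%%, 95%% LOA %.0f-%.0f%% (n = %d)\n",
              eq, ba$mean_ratio_pct, ba$loa_low_pct, ba$loa_high_pct, ba$n))
}

pdf("results/bland_altman.pdf", width = 9, height = 3.2)
op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
for (eq in names(report$equations)) {
  plot(report$equations[[eq]]$bland_altman, main = eq)
}
par(op)
invisible(dev.off())
cat("wrote results/bland_altman.pdf\n")

cat("\nground-truth recovery (Kawasaki prediction):\n")
rr <- recovery_report(full)
cat(sprintf("  %% below EAR: estimated %.1f%% vs true %.1f%%\n",
            rr$pct_below_ear_est, rr$pct_below_ear_true))
cat(sprintf("  Spearman rho (PrUIE vs mUIE): %.3f\n", rr$spearman_rho))
cat(sprintf("  Bland-Altman mean ratio: %.1f%%\n", rr$mean_ratio_pct))
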