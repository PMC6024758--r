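#!/usr/bin/env Rscript
# Step 2: screen collections and derive excretion/intake quantities.
#
# Applies the 24-h completeness criteria (volume <= 300 mL, or creatinine
# <= 4 mmol/day for women / <= 6 for men, excluded), predicts 24-h
# creatinine with the Tanaka, Kawasaki and Mage equations, extrapolates the
# spot iodine-to-creatinine ratio to predicted 24-h iodine excretion,
# computes measured 24-h excretion and the intake estimates, and writes the
# derived record table.

suppressPackageStartupMessages(library(iodstatus))

cohort <- read_cohort("results/cohort.csv")
derived <- derive_records(cohort)

n_excl <- sum(!derived$complete_collection)
cat("records in:", nrow(derived), "\n")
cat("incomplete 24-h collections excluded downstream:", n_excl, "\n")
kept <- derived[derived$complete_collection, ]
cat(sprintf("median PrCr (mg/day): tanaka %.0f, kawasaki %.0f, mage %.0f\n",
            median(kept$prcr_tanaka_mgday),
            median(kept$prcr_kawasaki_mgday),
            median(kept$prcr_mage_mgday, na.rm = TRUE)))
cat(sprintf("median PrUIE (ug/day): tanaka %.1f, kawasaki %.1f, mage %.1f\n",
            median(kept$pruie_tanaka_ugday),
            median(kept$pruie_kawasaki_ugday),
            median(kept$pruie_mage_ugday, na.rm = TRUE)))
cat(sprintf("median mUIE: %.1f ug/day\n", median(kept$muie_ugday)))

write.csv(derived, "results/derived_records.csv", row.names = FALSE, na = "")
cat("wrote results/derived_records.csv\n")
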