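#!/usr/bin/env Rscript
# Step 3: cohort report.
#
# Rolls the per-subject tables up into the cohort summary tables: facial
# proportions (per-sex mean, SD, percent of the divine ratio, Mann-Whitney
# p), RFV/RCV midline values (per-sex mean and SD), the smile-framework
# category frequencies (chi-square / Fisher sex association), and the
# landmark hierarchy. Writes results/report/.

suppressPackageStartupMessages(library(smileframe))

rep <- run_report("results/analysis", "results/cohort/demographics.csv",
                  out_dir = "results/report")

print(rep)
cat("\nFacial proportions closest to the divine ratio (total group):\n")
tot <- rep$proportions[rep$proportions$group == "total", ]
tot <- tot[order(abs(tot$golden_pct_of_mean - 100)), ]
for (i in seq_len(nrow(tot))) {
  cat(sprintf("  %-16s mean %.3f  (%.1f%% of 1.618)\n",
              tot$ratio[i], tot$mean[i], tot$golden_pct_of_mean[i]))
}
cat("\nSmile framework (total cohort):\n")
for (attr in unique(rep$smile$attribute)) {
  blk <- rep$smile[rep$smile$attribute == attr, ]
  top <- blk[which.max(blk$n), ]
  cat(sprintf("  %-14s most frequent: %s (%.1f%%)\n", attr, top$level,
              top$percent))
}
cat("\nTables written under results/report/\n")
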