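#!/usr/bin/env Rscript
# Step 1 — candidate reference genes at a glance.
# Per-gene descriptive statistics of the adipose-MSC Ct dataset: which
# candidates are abundant, which fluctuate, and whether everything
# amplified cleanly (Ct < 35).

library(refstab)
dir.create("results", showWarnings = FALSE)

asc <- asc_ct()
print(asc)

stopifnot(all(call_amplification(asc$ct)))
cat("\nAll", length(asc$ct), "measurements amplified (Ct < 35).\n\n")

d <- ct_descriptives(asc)
d[-1] <- round(d[-1], 2)
print(d, row.names = FALSE)

cat("\nMost abundant candidate:", d$gene[which.min(d$mean)],
    sprintf("(mean Ct %.2f)", min(d$mean)), "\n")
cat("Least abundant candidate:", d$gene[which.max(d$mean)],
    sprintf("(mean Ct %.2f)", max(d$mean)), "\n")
cat("Widest Ct range:", d$gene[which.max(d$range)],
    sprintf("(%.2f cycles)", max(d$range)),
    "- the first hint that it is condition-sensitive.\n")

write.csv(d, "results/descriptive_stats.csv", row.names = FALSE)
cat("\nwrote results/descriptive_stats.csv\n")
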