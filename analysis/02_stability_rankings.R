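#!/usr/bin/env Rscript
# Step 2 — the core result: stability rankings per condition, for coupled
# conditions, and over all samples, by four algorithms plus the
# geometric-mean consensus. The best reference gene turns out to be
# condition-specific; starvation reshuffles the ranking more than
# inflammation does.

library(refstab)
dir.create("results", showWarnings = FALSE)

asc <- asc_ct()
res <- run_plan(asc)          # the 12 analyses of the study design
print(res)

long <- as.data.frame(res)
long$value <- round(long$value, 4)
write.table(long, "results/stability_long.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cons <- do.call(rbind, lapply(res, function(e) {
  cbind(subset = e$label, as.data.frame(e$consensus))
}))
cons$geomean <- round(cons$geomean, 2)
write.table(cons, "results/consensus_rankings.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

all_cons <- res[["ALL"]]$consensus
cat(sprintf("\nAcross all 15 samples, %s is the most stable candidate (geomean %.2f)
and %s the least stable (%.2f).\n",
            all_cons$gene[1], all_cons$geomean[1],
            all_cons$gene[nrow(all_cons)], all_cons$geomean[nrow(all_cons)]))
gn <- res[["ALL"]]$stability$genorm
cat("geNorm best pair over all samples:",
    paste(attr(gn, "genorm_pair"), collapse = " | "), "\n")
cat("\nwrote results/stability_long.tsv, results/consensus_rankings.tsv\n")
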