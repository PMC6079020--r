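#!/usr/bin/env Rscript

# Stage 3: score the pipeline against the simulation's realized ground truth
# (what a perfect observer of the reads would compute with the same unit
# definitions): per-region absolute errors of the endemic unique fraction and
# the bipolar read share, the taxon-level category confusion matrix, and OTU
# purity against template ancestry.

library(snowbiogeo)

state <- readRDS("scratch/sim_state.rds")
res <- readRDS("scratch/pipeline_result.rds")

ev <- evaluate_recovery(res, state$tr)

write.table(ev$share_errors, "results/recovery_share_errors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(as.data.frame(ev$confusion), "results/recovery_confusion.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Recovery against realized truth:\n")
print(ev$share_errors, row.names = FALSE)
cat(sprintf("\nOTU purity: %.3f over %d OTUs\n", ev$otu_purity,
            length(res$otus$otus)))
cat("\nCategory confusion (rows = truth, columns = estimate):\n")
print(ev$confusion)
cat(sprintf("\nEstimated mean endemic unique fraction: %.1f%% (realized truth %.1f%%)\n",
            100 * ev$estimate_summary$overall$endemic_unique_fraction_mean,
            100 * ev$truth_summary$overall$endemic_unique_fraction_mean))
cat(sprintf("Estimated mean bipolar read share: %.1f%% (realized truth %.1f%%)\n",
            100 * ev$estimate_summary$overall$bipolar_read_share_mean,
            100 * ev$truth_summary$overall$bipolar_read_share_mean))
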