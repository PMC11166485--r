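#!/usr/bin/env Rscript
# Stage 2: tRNA pool summary statistics.
#
# Reads results/data/tgcn.tsv and computes, per species: total gene count,
# anticodon diversity, and the split of diversity into anticodons reading
# GC-ending versus AT-ending codons. Writes pool_summary.tsv and histogram
# tables of total pool size and diversity.

suppressMessages(library(trnapool))

tgcn <- load_tgcn_table("results/data/tgcn.tsv")
pool <- pool_summary(tgcn)
dir.create("results", showWarnings = FALSE)
write.table(pool, "results/pool_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Pool summaries for", nrow(pool), "species\n")
cat(sprintf("diversity: range %d-%d, median %g\n",
            min(pool$diversity), max(pool$diversity),
            median(pool$diversity)))
cat(sprintf("total tGCN: range %d-%d, median %g\n",
            min(pool$total_tgcn), max(pool$total_tgcn),
            median(pool$total_tgcn)))
cat(sprintf("mean GC-ending share of diversity: %.2f\n",
            mean(pool$gc_ending_diversity / pool$diversity)))
cat("wrote results/pool_summary.tsv\n")
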