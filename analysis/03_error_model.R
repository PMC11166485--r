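#!/usr/bin/env Rscript
# Stage 3: mechanistic missense-error model.
#
# Classifies all codon-anticodon pairs under the default bacterial wobble
# rules (G34:U3, U34:G3, inosine A34 pairing C/A/U; efficiency 0.64),
# converts each species' tGCN into per-codon cognate and near-cognate
# elongation rates, calibrates rates to a 12.5 aa/s harmonic mean, and
# computes per-codon missense error rates eps = RN / (RC + RN + RD) with
# RD = 3.146e-3 s^-1. Writes the per-species summary (median eps) and the
# full per-codon rate table.

suppressMessages(library(trnapool))

tgcn <- load_tgcn_table("results/data/tgcn.tsv")
nbhd <- build_codon_neighborhoods()
params <- model_params()
errs <- error_profiles(tgcn, nbhd, params)

write.table(errs, "results/error_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(attr(errs, "codon_rates"), "results/codon_rates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Error profiles for", nrow(errs), "species\n")
print(nbhd)
cat(sprintf("median missense rate across species: %.3g (range %.3g-%.3g)\n",
            median(errs$median_eps), min(errs$median_eps),
            max(errs$median_eps)))
cat(sprintf("species with unreadable codons (RC = 0): %d\n",
            sum(errs$n_unreadable > 0)))
cat("wrote results/error_profiles.tsv, results/codon_rates.tsv\n")
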