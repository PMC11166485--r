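#!/usr/bin/env Rscript
# Stage 4: phylogenetic regressions and independent contrasts.
#
# Joins the pool summaries and error profiles with the species metadata,
# prunes the tree to the shared species, and fits each response
# (diversity, total tGCN, median missense rate, GC-/AT-ending diversity)
# on temperature class + GC under both BM and OU covariance by ML,
# selecting by AIC (parsimony within 2 units). Also computes phylogenetic
# independent contrasts and their Spearman correlations for the headline
# trait pairs. Writes regressions.tsv / regressions.json /
# pic_spearman.tsv.

suppressMessages(library(trnapool))

pool <- read.delim("results/pool_summary.tsv")
errs <- read.delim("results/error_profiles.tsv")
meta <- load_species_metadata("results/data/metadata.tsv")
tree <- ape::read.tree("results/data/tree.nwk")

traits <- merge(merge(pool, errs[, c("species", "median_eps")],
                      by = "species"), meta, by = "species")
tree <- ape::keep.tip(tree, intersect(traits$species, tree$tip.label))
traits <- traits[match(tree$tip.label, traits$species), ]
cat("Fitting phylogenetic regressions for", nrow(traits), "species\n\n")

responses <- c("diversity", "total_tgcn", "median_eps",
               "gc_ending_diversity", "at_ending_diversity")
rows <- list()
js <- list()
for (resp in responses) {
  bm <- fit_phylo_lm(resp, traits, tree, model = "BM")
  ou <- fit_phylo_lm(resp, traits, tree, model = "OU")
  ch <- select_model(list(BM = bm, OU = ou))
  cat("=>", resp, ": chose", ch$model, sprintf("(delta AIC %.2f)\n",
                                               ch$delta_AIC))
  print(ch)
  cat("\n")
  rows[[resp]] <- data.frame(response = resp, model = ch$model,
                             ch$coefficients, sigma2 = unname(ch$sigma2),
                             alpha = unname(ch$alpha),
                             AIC = ch$AIC, delta_AIC = ch$delta_AIC,
                             adj_r2 = ch$adj_r2, n = ch$n)
  js[[resp]] <- list(model = ch$model, AIC = ch$AIC,
                     delta_AIC = ch$delta_AIC, alpha = ch$alpha,
                     sigma2 = ch$sigma2, adj_r2 = ch$adj_r2, n = ch$n,
                     coefficients = ch$coefficients)
}
write.table(do.call(rbind, c(rows, make.row.names = FALSE)),
            "results/regressions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(js, "results/regressions.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE, dataframe = "rows")

pairs <- list(c("diversity", "gc"), c("diversity", "median_eps"),
              c("median_eps", "gc"), c("gc_ending_diversity", "gc"),
              c("at_ending_diversity", "gc"))
pic_tab <- do.call(rbind, lapply(pairs, function(pr) {
  x1 <- setNames(traits[[pr[1]]], traits$species)
  x2 <- setNames(traits[[pr[2]]], traits$species)
  s <- spearman_pic(pic_contrasts(tree, x1), pic_contrasts(tree, x2))
  data.frame(trait1 = pr[1], trait2 = pr[2], rho = s$rho,
             p_value = s$p_value)
}))
write.table(pic_tab, "results/pic_spearman.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("PIC Spearman correlations:\n")
print(pic_tab, row.names = FALSE, digits = 3)
cat("\nwrote results/regressions.{tsv,json}, results/pic_spearman.tsv\n")
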