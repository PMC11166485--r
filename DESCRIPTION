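Package: trnapool
Title: Comparative Analysis of Bacterial tRNA Pools, Translation Errors,
    and Growth Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of bacterial tRNA gene copy
    number (tGCN) tables. Classifies codon-anticodon pairs as cognate,
    pseudo-cognate or near-cognate under configurable wobble rules;
    computes tRNA pool summary statistics (total gene count, anticodon
    diversity, diversity split by codon third position); estimates
    per-codon elongation and missense error rates from a mechanistic
    model of ribosome elongation; and fits phylogenetic linear
    regressions of pool statistics on GC content and temperature class
    under Brownian-motion and Ornstein-Uhlenbeck trait-evolution
    covariance, with AIC model selection and phylogenetic independent
    contrasts. Includes a synthetic-data generator producing ultrametric
    trees, species metadata and tGCN tables with known ground truth so
    the whole pipeline can be exercised and validated without external
    data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
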