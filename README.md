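# trnapool

Comparative analysis of bacterial tRNA pools: what do tRNA gene copy
numbers imply about translation errors, and how do tRNA pools evolve with
genomic GC content and growth temperature?

Bacteria carry fewer than the 61 possible sense anticodons because wobble
pairing lets one tRNA read several codons. This package is for
comparative genomicists who have, per species, a table of tRNA gene copy
numbers (tGCNs) by anticodon, genomic GC content, an optimal growth
temperature (or a psychrophile / mesophile / thermophile label), and a
time-calibrated phylogeny. It computes:

1. **Pool summaries** — total tRNA gene count, anticodon diversity, and
   the split of diversity into anticodons reading GC- versus AT-ending
   codons.
2. **Mechanistic missense-error rates** — every codon–anticodon pair is
   classified cognate / pseudo-cognate / near-cognate under configurable
   bacterial wobble rules (G34:U3, U34:G3, inosine A34); per-codon
   cognate and near-cognate elongation rates, linear in gene copy number,
   are calibrated so their harmonic mean is 12.5 aa/s, and the missense
   error rate is
   `eps(i) = RN(i) / (RC(i) + RN(i) + RD)` with drop-off rate
   `RD = 3.146e-3 s^-1`; a species is summarized by its median eps.
3. **Phylogenetic regressions** — each response is regressed on
   temperature class (mesophile as reference) and GC fraction,
   `y = beta_Meso + beta_Psychro * xPsychro + beta_Thermo * xThermo +
   beta_GC * GC + e`, with `e ~ N(0, sigma2 * V)` under Brownian-motion
   or Ornstein–Uhlenbeck covariance on the tree, fitted by maximum
   likelihood with AIC model selection, plus Spearman correlations of
   phylogenetic independent contrasts.

A synthetic-data generator (`simulate_dataset()`) produces ultrametric
trees, metadata and tGCN tables with known ground truth under the study
conditions (406 species, 334:5:67 class frequencies, GC in 0.26–0.74),
so the whole pipeline can be exercised and validated without any
external downloads.

## Worked example

```r
library(trnapool)

cfg <- pipeline_config(synthetic = list(n_species = 406, seed = 1), seed = 1)
report <- run_pipeline(cfg)
print(report$regressions$diversity$chosen)
```

```
Phylogenetic regression (OU), response: diversity, n = 406
       term estimate       se       t     p_value
1 intercept  29.3722 0.861044 34.1123 9.5404e-121
2  xPsychro  -1.4564 0.683267 -2.1315  3.3658e-02
3   xThermo   1.8169 0.093417 19.4493  7.2973e-60
4        gc  21.4750 1.293977 16.5961  1.7336e-47
sigma2 = 19.299, alpha = 1.3037, logLik = -750.612 , AIC = 1513.22 , adj R2 = 0.6129
```

The dataset was generated with a true thermophile offset of +1.77
anticodons and a true GC slope of 21.43; the OU fit (preferred over BM
by 11.7 AIC units here) recovers both within one standard error:
thermophiles carry about 1.8 more anticodons than mesophiles of equal
GC, and a 10-point GC increase adds about 2.1 anticodons. The contrast
correlations mirror the trait-level relationships:

```r
print(report$pic_spearman)
```

```
               trait1     trait2      rho   p_value
1           diversity         gc  0.54412 1.374e-32
2           diversity median_eps -0.17815 3.145e-04
3          median_eps         gc -0.07558 1.289e-01
4 gc_ending_diversity         gc  0.57185 1.522e-36
5 at_ending_diversity         gc -0.27819 1.242e-08
```

Diversity rises with GC, and that rise is carried by anticodons reading
GC-ending codons (rho 0.57) rather than AT-ending ones (rho −0.28).

Real data run the same way through file paths:

```r
cfg <- pipeline_config(inputs = list(tgcn = "tgcn.tsv",
                                     metadata = "metadata.tsv",
                                     tree = "tree.nwk"),
                       out_dir = "results")
report <- run_pipeline(cfg)
```

The `analysis/` directory holds the same workflow as numbered stage
scripts (`01_simulate.R` … `05_report.R`), each a thin driver over the
package functions that writes its tables under `results/`.

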