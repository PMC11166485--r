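# Shared fixtures and independent oracles used across test files.

# A tiny tGCN table with known summaries.
make_toy_tgcn <- function() {
  acs <- sense_anticodons()
  m <- matrix(0L, 3, length(acs), dimnames = list(c("spA", "spB", "spC"),
                                                  acs))
  m["spA", c("AGC", "UGC", "CAU")] <- c(4L, 2L, 1L)
  m["spB", acs] <- 1L
  m["spC", c("GGC", "CGC")] <- c(3L, 5L)
  tgcn_table(m)
}

# Independent brute-force codon-anticodon classifier. Works from first
# principles on strings and the code table; shares no code with
# classify_pairing().
brute_force_classify <- function(codon, anticodon, rules = wobble_rules()) {
  code <- genetic_code()
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  cb <- strsplit(codon, "")[[1]]
  ab <- strsplit(anticodon, "")[[1]]
  aa_codon <- code[[codon]]
  aa_anti <- code[[paste(comp[rev(ab)], collapse = "")]]
  # position matches: codon pos k pairs anticodon base ab[4-k]
  m1 <- comp[cb[1]] == ab[3]
  m2 <- comp[cb[2]] == ab[2]
  wob <- rules$pairs
  m3 <- comp[cb[3]] == ab[1] ||
    any(wob$ac34 == ab[1] & wob$c3 == cb[3])
  if (aa_codon == aa_anti) {
    if (m1 && m2 && m3) "COGNATE" else "PSEUDO_COGNATE"
  } else if (sum(!c(m1, m2, m3)) == 1) {
    "NEAR_COGNATE"
  } else {
    "NON_COGNATE"
  }
}

# Simple regression dataset on a simulated tree, for phylo_lm tests.
make_regression_data <- function(n = 40, seed = 42, beta = c(2, 0.5),
                                 sigma2 = 1, model = "BM", alpha = 1) {
  tree <- simulate_tree(n, seed = seed)
  set.seed(seed + 1000)
  x <- rnorm(n)
  X <- cbind(intercept = 1, x = x)
  rownames(X) <- tree$tip.label
  V <- if (model == "BM") bm_covariance(tree) else ou_covariance(tree, alpha)
  y <- drop(X %*% beta) + sqrt(sigma2) * drop(t(chol(V)) %*% rnorm(n))
  names(y) <- tree$tip.label
  list(tree = tree, X = X, y = y, x = setNames(x, tree$tip.label))
}
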