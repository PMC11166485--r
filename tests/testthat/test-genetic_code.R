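test_that("reverse-complement conventions are respected", {
  expect_equal(wc_codon_for_anticodon("AGC"), "GCU")
  expect_equal(wc_codon_for_anticodon("CAU"), "AUG")
  expect_equal(wc_codon_for_anticodon("UUU"), "AAA")
  expect_equal(wc_anticodon_for_codon("GCU"), "AGC")
  expect_error(wc_codon_for_anticodon("AG"), "3 bases")
  expect_error(wc_codon_for_anticodon("AGT"), "outside")
  # the anticodon universe is the reverse complement of the sense codons
  expect_length(sense_codons(), 61)
  expect_length(sense_anticodons(), 61)
  expect_setequal(vapply(sense_anticodons(), wc_codon_for_anticodon,
                         character(1)), sense_codons())
  expect_false(any(c("UUA", "CUA", "UCA") %in% sense_anticodons()))
})

test_that("pairing classification matches the worked cases", {
  expect_equal(classify_pairing("GCU", "AGC"), "COGNATE")     # WC, both Ala
  expect_equal(classify_pairing("GCC", "AGC"), "COGNATE")     # inosine A34:C3
  expect_equal(classify_pairing("AAA", "GUU"), "NEAR_COGNATE") # Lys vs Asn
  expect_equal(classify_pairing("CGG", "ACG"), "PSEUDO_COGNATE") # both Arg
  # wobble pairs count: G34:U3 cognate
  expect_equal(classify_pairing("GCU", "GGC"), "COGNATE")
  expect_error(classify_pairing("UAA", "AGC"), "stop codon")
  expect_error(classify_pairing("GCU", "UUA"), "stop")
  rules_lenient <- wobble_rules(strict_anticodons = FALSE)
  expect_warning(k <- classify_pairing("GCU", "UUA", rules = rules_lenient),
                 "stop")
  expect_equal(k, "NON_COGNATE")
})

test_that("inosine flag controls A34 wobble pairing", {
  off <- wobble_rules(inosine_a34 = FALSE)
  expect_equal(classify_pairing("GCC", "AGC", rules = off),
               "PSEUDO_COGNATE")
  on <- wobble_rules(inosine_a34 = TRUE)
  expect_equal(classify_pairing("GCC", "AGC", rules = on), "COGNATE")
  # A34:A3 also allowed under inosine
  expect_equal(classify_pairing("GCA", "AGC", rules = on), "COGNATE")
  # but A34:G3 is never a wobble pair
  expect_equal(classify_pairing("GCG", "AGC", rules = on),
               "PSEUDO_COGNATE")
})

test_that("Watson-Crick-only rules give a cognate bijection", {
  wc_only <- wobble_rules(pairs = data.frame(ac34 = character(),
                                             c3 = character(),
                                             weight = numeric()),
                          inosine_a34 = FALSE)
  nb <- build_codon_neighborhoods(rules = wc_only)
  n_cognate_per_codon <- rowSums(nb$class == "COGNATE")
  expect_true(all(n_cognate_per_codon == 1))
  n_codons_per_anticodon <- colSums(nb$class == "COGNATE")
  expect_true(all(n_codons_per_anticodon == 1))
})

test_that("exhaustive 61x61 classification agrees with a brute-force oracle", {
  rules <- wobble_rules()
  nb <- build_codon_neighborhoods(rules = rules)
  code <- genetic_code()
  for (cd in sense_codons()) {
    for (ac in sense_anticodons()) {
      expect_equal(nb$class[cd, ac], brute_force_classify(cd, ac, rules),
                   label = paste(cd, ac))
    }
  }
})

test_that("classification is a partition with amino-acid consistency", {
  nb <- build_codon_neighborhoods()
  code <- genetic_code()
  expect_true(all(nb$class %in% c("COGNATE", "PSEUDO_COGNATE",
                                  "NEAR_COGNATE", "NON_COGNATE")))
  for (cd in sense_codons()) {
    aa_cd <- code[[cd]]
    for (ac in sense_anticodons()) {
      aa_ac <- code[[wc_codon_for_anticodon(ac)]]
      k <- nb$class[cd, ac]
      if (k %in% c("COGNATE", "PSEUDO_COGNATE")) {
        expect_identical(aa_cd, aa_ac, label = paste(cd, ac, k))
      }
      if (k == "NEAR_COGNATE") {
        expect_false(identical(aa_cd, aa_ac), label = paste(cd, ac))
      }
    }
  }
})

test_that("adding a wobble rule grows cognate sets monotonically", {
  base_rules <- wobble_rules(pairs = data.frame(ac34 = "G", c3 = "U",
                                                weight = 0.64),
                             inosine_a34 = FALSE)
  bigger <- wobble_rules(pairs = data.frame(ac34 = c("G", "U"),
                                            c3 = c("U", "G"),
                                            weight = 0.64),
                         inosine_a34 = TRUE)
  nb1 <- build_codon_neighborhoods(rules = base_rules)
  nb2 <- build_codon_neighborhoods(rules = bigger)
  was_cognate <- nb1$class == "COGNATE"
  expect_true(all(nb2$class[was_cognate] == "COGNATE"))
})

test_that("neighborhood weights follow the rules", {
  nb <- build_codon_neighborhoods(noncognate_weight = 0.5)
  # WC cognate weight 1
  expect_equal(nb$weight["GCU", "AGC"], 1)
  # wobble cognate weight = efficiency
  expect_equal(nb$weight["GCU", "GGC"], 0.64)
  # near-cognate weight configurable
  expect_equal(nb$weight["AAA", "GUU"], 0.5)
  sets <- codon_neighbors(nb, "GCU")
  expect_true(all(c("cognate", "pseudo_cognate", "near_cognate") %in%
                  names(sets)))
  expect_true("AGC" %in% sets$cognate$anticodon)
  expect_equal(length(intersect(sets$cognate$anticodon,
                                sets$near_cognate$anticodon)), 0)
})

test_that("lysidine toggle reassigns CAU to isoleucine", {
  ile_rules <- wobble_rules(cau_as_ile = TRUE)
  # CAU no longer cognate to AUG (Met codon, Ile anticodon, perfect WC pair
  # but wrong amino acid and zero mismatches -> non-cognate)
  expect_equal(classify_pairing("AUG", "CAU", rules = ile_rules),
               "NON_COGNATE")
  # and is now pseudo-cognate to the Ile codon AUU (third position C:U
  # disallowed)
  expect_equal(classify_pairing("AUU", "CAU", rules = ile_rules),
               "PSEUDO_COGNATE")
  # default: Met anticodon, cognate to AUG only
  expect_equal(classify_pairing("AUG", "CAU"), "COGNATE")
})

test_that("wobble rule sets load from YAML and JSON", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("wobble_efficiency: 0.41",
               "inosine_a34: false",
               "pairs:",
               "  - {ac34: G, c3: U, weight: 0.41}"), yml)
  r <- read_wobble_rules(yml)
  expect_equal(r$wobble_efficiency, 0.41)
  expect_false(r$inosine_a34)
  expect_equal(classify_pairing("GCU", "GGC", rules = r), "COGNATE")
  expect_equal(classify_pairing("GCC", "AGC", rules = r), "PSEUDO_COGNATE")
  js <- withr::local_tempfile(fileext = ".json")
  writeLines('{"wobble_efficiency": 0.3, "cau_as_ile": true}', js)
  r2 <- read_wobble_rules(js)
  expect_equal(r2$wobble_efficiency, 0.3)
  expect_true(r2$cau_as_ile)
})
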