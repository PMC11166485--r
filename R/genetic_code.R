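# RNA alphabet helpers ------------------------------------------------------

RNA_BASES <- c("A", "C", "G", "U")

.rna_complement <- c(A = "U", C = "G", G = "C", U = "A")

.check_triplet <- function(x, what = "triplet") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (nchar(x) != 3L) {
    stop(what, " '", x, "' must have exactly 3 bases", call. = FALSE)
  }
  b <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (!all(b %in% RNA_BASES)) {
    stop(what, " '", x, "' contains bases outside {A,C,G,U}", call. = FALSE)
  }
  b
}

#' Convert a DNA-alphabet triplet to RNA
#'
#' Replaces T with U and upper-cases. Used so tGCN tables written in the DNA
#' alphabet are accepted transparently.
#'
#' @param x character vector of triplets.
#' @return character vector in the RNA alphabet.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' The standard genetic code in the RNA alphabet
#'
#' Returns the standard genetic code as a named character vector mapping each
#' of the 64 codons (RNA alphabet, 5'->3') to a one-letter amino acid, with
#' `"*"` marking the three stop codons (UAA, UAG, UGA). The sense/stop
#' structure of the standard code is identical to the bacterial code for
#' these 64 assignments.
#'
#' @return named character vector of length 64.
#' @export
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- as_rna(names(gc))
  gc
}

#' Sense codons and sense anticodons
#'
#' The 61 sense codons are the 64 codons minus the three stops. The 61 valid
#' sense anticodons are their reverse complements; the three anticodons whose
#' Watson-Crick codon is a stop (UUA, CUA, UCA) are excluded from the
#' universe.
#'
#' @return character vector of length 61, sorted.
#' @export
sense_codons <- function() {
  gc <- genetic_code()
  sort(names(gc)[gc != "*"])
}

#' @rdname sense_codons
#' @export
sense_anticodons <- function() {
  sort(vapply(sense_codons(), wc_anticodon_for_codon, character(1),
              USE.NAMES = FALSE))
}

#' Watson-Crick partner of an anticodon (or codon)
#'
#' Anticodons are written 5'->3': the FIRST character is tRNA position 34 and
#' pairs the codon's third (wobble) position. The Watson-Crick codon of an
#' anticodon is therefore its reverse complement in the RNA alphabet, and
#' vice versa.
#'
#' @param anticodon,codon a 3-letter RNA string.
#' @return the reverse-complement triplet.
#' @export
wc_codon_for_anticodon <- function(anticodon) {
  b <- .check_triplet(anticodon, "anticodon")
  paste(.rna_complement[rev(b)], collapse = "")
}

#' @rdname wc_codon_for_anticodon
#' @export
wc_anticodon_for_codon <- function(codon) {
  b <- .check_triplet(codon, "codon")
  paste(.rna_complement[rev(b)], collapse = "")
}

# Wobble rules --------------------------------------------------------------

#' Construct a wobble rule set
#'
#' A wobble rule set lists the third-position pairs (anticodon position 34
#' base, codon position 3 base) that are allowed beyond Watson-Crick, each
#' with an efficiency weight in (0, 1] relative to a Watson-Crick pair
#' (weight 1). The default bacterial set allows G34:U3 and U34:G3 and treats
#' anticodon position 34 A as inosine, which pairs codon third positions C, A
#' and U (U being the Watson-Crick partner).
#'
#' @param pairs data.frame with columns `ac34`, `c3`, `weight` giving allowed
#'   non-Watson-Crick third-position pairs. Defaults to G34:U3 and U34:G3 at
#'   `wobble_efficiency`.
#' @param inosine_a34 treat anticodon-34 A as inosine (adds A34:C3 and A34:A3
#'   at `wobble_efficiency`).
#' @param wobble_efficiency default efficiency weight for wobble pairs,
#'   in (0, 1].
#' @param cau_as_ile if TRUE, the anticodon CAU is counted as isoleucine
#'   (the lysidine-modified bacterial Ile2 tRNA) instead of methionine.
#'   Default FALSE: CAU is cognate to AUG only.
#' @param strict_anticodons reject stop-decoding anticodons (UUA, CUA, UCA)
#'   with an error; if FALSE they are dropped with a warning where tables are
#'   read.
#' @return an object of class `wobble_rules`.
#' @export
wobble_rules <- function(pairs = NULL,
                         inosine_a34 = TRUE,
                         wobble_efficiency = 0.64,
                         cau_as_ile = FALSE,
                         strict_anticodons = TRUE) {
  if (!is.numeric(wobble_efficiency) || wobble_efficiency <= 0 ||
      wobble_efficiency > 1) {
    stop("wobble_efficiency must be in (0, 1]", call. = FALSE)
  }
  if (is.null(pairs)) {
    pairs <- data.frame(ac34 = c("G", "U"), c3 = c("U", "G"),
                        weight = wobble_efficiency)
  }
  stopifnot(all(c("ac34", "c3", "weight") %in% names(pairs)))
  if (isTRUE(inosine_a34)) {
    pairs <- rbind(pairs, data.frame(ac34 = c("A", "A"), c3 = c("C", "A"),
                                     weight = wobble_efficiency))
  }
  pairs$ac34 <- as_rna(pairs$ac34)
  pairs$c3 <- as_rna(pairs$c3)
  if (any(pairs$weight <= 0 | pairs$weight > 1)) {
    stop("all wobble weights must be in (0, 1]", call. = FALSE)
  }
  wc <- pairs$ac34 == .rna_complement[pairs$c3]
  pairs <- pairs[!wc, , drop = FALSE]  # WC pairs are implicit with weight 1
  structure(list(pairs = pairs,
                 inosine_a34 = isTRUE(inosine_a34),
                 wobble_efficiency = wobble_efficiency,
                 cau_as_ile = isTRUE(cau_as_ile),
                 strict_anticodons = isTRUE(strict_anticodons)),
            class = "wobble_rules")
}

#' Read a wobble rule set from a YAML or JSON config file
#'
#' The file may contain the keys `pairs` (list of `{ac34, c3, weight}`
#' records), `inosine_a34`, `wobble_efficiency`, `cau_as_ile` and
#' `strict_anticodons`; missing keys take the [wobble_rules()] defaults.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return an object of class `wobble_rules`.
#' @export
read_wobble_rules <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pairs <- NULL
  if (!is.null(cfg$pairs)) {
    pairs <- as.data.frame(do.call(rbind, lapply(cfg$pairs, function(p) {
      data.frame(ac34 = p$ac34, c3 = p$c3, weight = as.numeric(p$weight))
    })))
    if (is.data.frame(cfg$pairs)) pairs <- cfg$pairs
  }
  args <- list(pairs = pairs)
  for (k in c("inosine_a34", "wobble_efficiency", "cau_as_ile",
              "strict_anticodons")) {
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  }
  do.call(wobble_rules, args)
}

# third-position pair allowed (WC or wobble)? returns weight or NA
.third_position_weight <- function(ac34, c3, rules) {
  if (.rna_complement[c3] == ac34) return(1)
  hit <- rules$pairs$ac34 == ac34 & rules$pairs$c3 == c3
  if (any(hit)) rules$pairs$weight[which(hit)[1L]] else NA_real_
}

# amino acid delivered by an anticodon = translation of its WC codon,
# with the optional lysidine CAU-as-Ile override
.anticodon_amino_acid <- function(anticodon, code, rules) {
  if (rules$cau_as_ile && anticodon == "CAU") return("I")
  unname(code[wc_codon_for_anticodon(anticodon)])
}

#' Classify a codon-anticodon pair
#'
#' Implements the cognate / pseudo-cognate / near-cognate partition used to
#' drive the elongation model:
#' \itemize{
#'   \item COGNATE: codon positions 1-2 pair Watson-Crick, position 3 pairs
#'     Watson-Crick or by an allowed wobble rule, and the anticodon delivers
#'     the codon's amino acid.
#'   \item PSEUDO_COGNATE: the anticodon delivers the correct amino acid but
#'     the pairing is not Watson-Crick/wobble.
#'   \item NEAR_COGNATE: exactly one position mismatches (at positions 1-2
#'     only Watson-Crick counts as a match; at position 3 Watson-Crick or an
#'     allowed wobble pair counts) and the amino acids differ.
#'   \item NON_COGNATE: anything else.
#' }
#' An anticodon's amino acid is the translation of its Watson-Crick codon.
#'
#' @param codon a sense codon (RNA, 5'->3').
#' @param anticodon a sense anticodon (RNA, 5'->3'; first base = position 34).
#' @param code genetic code table from [genetic_code()].
#' @param rules a [wobble_rules()] object.
#' @return one of `"COGNATE"`, `"PSEUDO_COGNATE"`, `"NEAR_COGNATE"`,
#'   `"NON_COGNATE"`.
#' @export
classify_pairing <- function(codon, anticodon, code = genetic_code(),
                             rules = wobble_rules()) {
  cb <- .check_triplet(codon, "codon")
  ab <- .check_triplet(anticodon, "anticodon")
  if (code[codon] == "*") {
    stop("'", codon, "' is a stop codon; classification is over the 61 ",
         "sense codons", call. = FALSE)
  }
  if (code[wc_codon_for_anticodon(anticodon)] == "*") {
    msg <- paste0("anticodon '", anticodon, "' decodes a stop codon and is ",
                  "outside the 61-anticodon universe")
    if (rules$strict_anticodons) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    return("NON_COGNATE")
  }
  # anticodon base pairing codon position k is ab[4 - k]
  wc12 <- (.rna_complement[cb[1L]] == ab[3L]) &&
          (.rna_complement[cb[2L]] == ab[2L])
  w3 <- .third_position_weight(ab[1L], cb[3L], rules)
  same_aa <- .anticodon_amino_acid(anticodon, code, rules) ==
    unname(code[codon])
  if (same_aa) {
    if (wc12 && !is.na(w3)) return("COGNATE")
    return("PSEUDO_COGNATE")
  }
  mismatches <- sum(.rna_complement[cb[1L]] != ab[3L],
                    .rna_complement[cb[2L]] != ab[2L],
                    is.na(w3))
  if (mismatches == 1L) "NEAR_COGNATE" else "NON_COGNATE"
}

#' Classify all anticodons against all sense codons
#'
#' Runs [classify_pairing()] over the full 61 x 61 grid of sense codons and
#' sense anticodons and attaches binding weights: 1 for Watson-Crick
#' cognates, the rule's efficiency for wobble cognates, and
#' `noncognate_weight` for near- and pseudo-cognates. The result drives the
#' per-codon elongation rates.
#'
#' @param code genetic code table from [genetic_code()].
#' @param rules a [wobble_rules()] object.
#' @param noncognate_weight weight attached to near- and pseudo-cognate
#'   pairs (the elongation model scales these again by its own kinetic
#'   near-cognate weight; keep one of the two at 1).
#' @return object of class `codon_neighborhoods`: a list with `class` and
#'   `weight` matrices (codons x anticodons) plus the inputs. Use
#'   [codon_neighbors()] to extract the per-codon sets.
#' @export
build_codon_neighborhoods <- function(code = genetic_code(),
                                      rules = wobble_rules(),
                                      noncognate_weight = 1) {
  codons <- sense_codons()
  acs <- sense_anticodons()
  cls <- matrix("NON_COGNATE", length(codons), length(acs),
                dimnames = list(codons, acs))
  wt <- matrix(0, length(codons), length(acs),
               dimnames = list(codons, acs))
  for (cd in codons) {
    cb <- strsplit(cd, "")[[1L]]
    for (ac in acs) {
      k <- classify_pairing(cd, ac, code, rules)
      cls[cd, ac] <- k
      if (k == "COGNATE") {
        wt[cd, ac] <- .third_position_weight(substr(ac, 1L, 1L), cb[3L],
                                             rules)
      } else if (k %in% c("NEAR_COGNATE", "PSEUDO_COGNATE")) {
        wt[cd, ac] <- noncognate_weight
      }
    }
  }
  structure(list(class = cls, weight = wt, rules = rules,
                 noncognate_weight = noncognate_weight),
            class = "codon_neighborhoods")
}

#' Per-codon cognate / pseudo-cognate / near-cognate sets
#'
#' @param nbhd a `codon_neighborhoods` object.
#' @param codon a sense codon.
#' @return list with elements `cognate`, `pseudo_cognate`, `near_cognate`,
#'   each a data.frame with columns `anticodon` and `weight`.
#' @export
codon_neighbors <- function(nbhd, codon) {
  stopifnot(inherits(nbhd, "codon_neighborhoods"))
  codon <- as_rna(codon)
  if (!codon %in% rownames(nbhd$class)) {
    stop("'", codon, "' is not a sense codon", call. = FALSE)
  }
  out <- lapply(c(cognate = "COGNATE", pseudo_cognate = "PSEUDO_COGNATE",
                  near_cognate = "NEAR_COGNATE"), function(k) {
    sel <- nbhd$class[codon, ] == k
    data.frame(anticodon = colnames(nbhd$class)[sel],
               weight = unname(nbhd$weight[codon, sel]))
  })
  out
}

#' @export
print.codon_neighborhoods <- function(x, ...) {
  tab <- table(factor(x$class, c("COGNATE", "PSEUDO_COGNATE",
                                 "NEAR_COGNATE", "NON_COGNATE")))
  cat("Codon-anticodon neighborhoods over", nrow(x$class), "sense codons x",
      ncol(x$class), "sense anticodons\n")
  cat("  pair counts:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  cat("  wobble efficiency:", x$rules$wobble_efficiency,
      "| inosine A34:", x$rules$inosine_a34, "\n")
  invisible(x)
}
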