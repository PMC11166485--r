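# Mechanistic elongation / missense-error model ----------------------------

#' Parameters of the elongation model
#'
#' @param RD ribosome drop-off rate (s^-1), the rate of premature
#'   translation termination; applied uniformly to all codons.
#' @param target_harmonic_mean calibration target for the harmonic mean of
#'   the cognate elongation rates across codons, in amino acids per second.
#' @param rate_constant base association rate per gene copy (s^-1) before
#'   calibration. Its value is irrelevant after harmonic-mean scaling; kept
#'   at 1.
#' @param noncognate_weight kinetic weight of near-cognate (and
#'   pseudo-cognate) binding relative to a Watson-Crick cognate. The default
#'   1e-3 represents the effective probability that a near-cognate ternary
#'   complex survives selection and proofreading, and puts missense error
#'   rates in the empirically observed 1e-3 to 1e-4 per-codon range.
#' @param pseudo_mode `"exclude"` uses the literal error-rate formula
#'   eps = RN / (RC + RN + RD); `"in_denominator"` adds the pseudo-cognate
#'   rate RP to the denominator.
#' @param harmonic_mean_over `"RC"` calibrates on the cognate elongation
#'   rate alone (successful incorporation); `"RC+RN"` includes near-cognate
#'   flux.
#' @return list of class `model_params`.
#' @export
model_params <- function(RD = 3.146e-3,
                         target_harmonic_mean = 12.5,
                         rate_constant = 1,
                         noncognate_weight = 1e-3,
                         pseudo_mode = c("exclude", "in_denominator"),
                         harmonic_mean_over = c("RC", "RC+RN")) {
  pseudo_mode <- match.arg(pseudo_mode)
  harmonic_mean_over <- match.arg(harmonic_mean_over)
  stopifnot(RD > 0, target_harmonic_mean > 0, rate_constant > 0,
            noncognate_weight > 0, noncognate_weight <= 1)
  structure(list(RD = RD, target_harmonic_mean = target_harmonic_mean,
                 rate_constant = rate_constant,
                 noncognate_weight = noncognate_weight,
                 pseudo_mode = pseudo_mode,
                 harmonic_mean_over = harmonic_mean_over),
            class = "model_params")
}

#' Unscaled per-codon elongation rates from one species' tGCN
#'
#' For each sense codon i, the cognate rate is
#' RC(i) = rate_constant * sum over cognate anticodons j of
#' weight(i, j) * tGCN(j); the near-cognate rate RN(i) and pseudo-cognate
#' rate RP(i) are the analogous sums over near- and pseudo-cognate
#' anticodons, additionally multiplied by `noncognate_weight`. All rates are
#' linear in the gene copy counts.
#'
#' @param row named numeric vector of anticodon counts (one `tgcn_table`
#'   row).
#' @param nbhd a `codon_neighborhoods` object.
#' @param params a [model_params()] object.
#' @return data.frame with columns `codon`, `RC`, `RN`, `RP`.
#' @export
compute_codon_rates <- function(row, nbhd, params = model_params()) {
  stopifnot(inherits(nbhd, "codon_neighborhoods"))
  acs <- colnames(nbhd$class)
  n <- numeric(length(acs))
  names(n) <- acs
  common <- intersect(names(row), acs)
  n[common] <- row[common]
  wt <- nbhd$weight
  rc <- params$rate_constant * as.vector((wt * (nbhd$class == "COGNATE")) %*% n)
  rn <- params$rate_constant * params$noncognate_weight *
    as.vector((wt * (nbhd$class == "NEAR_COGNATE")) %*% n)
  rp <- params$rate_constant * params$noncognate_weight *
    as.vector((wt * (nbhd$class == "PSEUDO_COGNATE")) %*% n)
  data.frame(codon = rownames(nbhd$class), RC = rc, RN = rn, RP = rp,
             row.names = NULL)
}

#' Calibrate elongation rates by harmonic mean
#'
#' Applies one multiplicative factor to RC, RN and RP so that the harmonic
#' mean of the cognate elongation rates across codons equals
#' `target_harmonic_mean` (12.5 amino acids per second by default). Codons
#' with RC = 0 (unreadable under the rule set) are excluded from the
#' harmonic mean, which is undefined at zero.
#'
#' @param rates data.frame from [compute_codon_rates()].
#' @param params a [model_params()] object.
#' @return list with `rates` (scaled data.frame) and `factor` (the scalar
#'   applied).
#' @export
scale_elongation_rates <- function(rates, params = model_params()) {
  base <- if (params$harmonic_mean_over == "RC") rates$RC else
    rates$RC + rates$RN
  pos <- base > 0
  if (!any(pos)) {
    stop("all cognate elongation rates are zero; species unanalyzable",
         call. = FALSE)
  }
  hmean <- sum(pos) / sum(1 / base[pos])
  factor <- params$target_harmonic_mean / hmean
  rates$RC <- rates$RC * factor
  rates$RN <- rates$RN * factor
  rates$RP <- rates$RP * factor
  list(rates = rates, factor = factor)
}

#' Missense error rate for one codon
#'
#' eps = RN / (RC + RN + RD), the probability that an elongation event
#' incorporates the wrong amino acid; with
#' `pseudo_mode = "in_denominator"` the pseudo-cognate rate RP joins the
#' denominator. The drop-off rate RD keeps the denominator positive, so eps
#' is always in `[0, 1)`.
#'
#' @param RC,RN,RP non-negative rates (s^-1); vectors recycle.
#' @param params a [model_params()] object.
#' @return numeric vector of error rates.
#' @export
missense_error_rate <- function(RC, RN, RP = 0, params = model_params()) {
  stopifnot(all(RC >= 0), all(RN >= 0))
  denom <- RC + RN + params$RD
  if (params$pseudo_mode == "in_denominator") denom <- denom + RP
  RN / denom
}

#' Full error profile for one species
#'
#' Chains [compute_codon_rates()], [scale_elongation_rates()] and
#' [missense_error_rate()]: rates are calibrated to the target harmonic mean
#' first, then per-codon error rates are computed on the calibrated scale
#' (RD is an absolute rate, so eps is only meaningful after calibration).
#' The species summary is the unweighted median of eps over all 61 sense
#' codons; codons with RC = 0 contribute eps = RN / (RN + RD).
#'
#' @param row named numeric vector of anticodon counts.
#' @param nbhd a `codon_neighborhoods` object.
#' @param params a [model_params()] object.
#' @return list with `rates` (codon, RC, RN, RP, eps), `factor`,
#'   `median_eps`.
#' @export
species_error_profile <- function(row, nbhd, params = model_params()) {
  scaled <- scale_elongation_rates(compute_codon_rates(row, nbhd, params),
                                   params)
  r <- scaled$rates
  r$eps <- missense_error_rate(r$RC, r$RN, r$RP, params)
  list(rates = r, factor = scaled$factor,
       median_eps = stats::median(r$eps))
}

#' Error profiles for every species in a tGCN table
#'
#' @param tgcn a `tgcn_table`.
#' @param nbhd a `codon_neighborhoods` object (default bacterial rules).
#' @param params a [model_params()] object.
#' @return data.frame with columns `species`, `median_eps`,
#'   `scaling_factor`, `n_unreadable` (codons with RC = 0); the per-codon
#'   table for all species is attached as attribute `"codon_rates"` (long
#'   data.frame: species, codon, RC, RN, eps).
#' @export
error_profiles <- function(tgcn, nbhd = build_codon_neighborhoods(),
                           params = model_params()) {
  profs <- lapply(rownames(tgcn), function(sp) {
    p <- species_error_profile(tgcn[sp, ], nbhd, params)
    list(summary = data.frame(species = sp, median_eps = p$median_eps,
                              scaling_factor = p$factor,
                              n_unreadable = sum(p$rates$RC == 0)),
         rates = data.frame(species = sp,
                            p$rates[, c("codon", "RC", "RN", "eps")]))
  })
  out <- do.call(rbind, lapply(profs, `[[`, "summary"))
  rownames(out) <- NULL
  attr(out, "codon_rates") <- do.call(rbind, lapply(profs, `[[`, "rates"))
  out
}
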