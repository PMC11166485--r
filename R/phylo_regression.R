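# Phylogenetic GLS regression under BM / OU covariance ---------------------

#' Check a phylogeny for the analyses in this package
#'
#' Requires a rooted tree with unique tip labels, non-negative branch
#' lengths and (for OU covariance) root-to-tip distances equal within a
#' relative tolerance.
#'
#' @param tree an [ape::phylo] object.
#' @param require_ultrametric enforce equal root-to-tip distances.
#' @param tol relative tolerance on root-to-tip distances.
#' @return the tree, invisibly.
#' @export
validate_phylogeny <- function(tree, require_ultrametric = TRUE,
                               tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths",
                                      call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels",
                                          call. = FALSE)
  if (require_ultrametric) {
    d <- tree_tip_depths(tree)
    if ((max(d) - min(d)) > tol * max(d)) {
      stop("tree is not ultrametric within tolerance", call. = FALSE)
    }
  }
  invisible(tree)
}

#' Root-to-tip distances
#' @param tree an [ape::phylo] object.
#' @return named numeric vector over tips.
#' @export
tree_tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Design matrix for the temperature-class + GC regression
#'
#' Columns are `intercept`, `xPsychro`, `xThermo`, `gc`, with mesophile as
#' the reference class: the intercept is the mesophile mean and the two
#' indicator coefficients are offsets relative to mesophiles.
#'
#' @param metadata data.frame with columns `species`, `gc`, `temp_class`.
#' @return numeric matrix with one row per species (rownames = species).
#' @export
design_matrix <- function(metadata) {
  bad <- !metadata$temp_class %in% TEMP_CLASSES
  if (any(bad)) {
    stop("unknown temp_class label(s): ",
         paste(unique(metadata$temp_class[bad]), collapse = ", "),
         call. = FALSE)
  }
  X <- cbind(intercept = 1,
             xPsychro = as.numeric(metadata$temp_class == "psychrophile"),
             xThermo = as.numeric(metadata$temp_class == "thermophile"),
             gc = metadata$gc)
  rownames(X) <- metadata$species
  X
}

#' Brownian-motion covariance of tip values
#'
#' Under Brownian motion with unit rate, the covariance between two tips is
#' the shared branch length from the root to their most recent common
#' ancestor; the variance of a tip is its root-to-tip distance.
#'
#' @param tree an [ape::phylo] object.
#' @return symmetric matrix (tips x tips), per unit sigma^2.
#' @export
bm_covariance <- function(tree) {
  validate_phylogeny(tree, require_ultrametric = FALSE)
  ape::vcv(tree)
}

#' Ornstein-Uhlenbeck covariance of tip values (fixed root)
#'
#' For an ultrametric tree of depth T, with t_ij the shared time of tips i
#' and j, the fixed-root OU covariance per unit sigma^2 is
#' `V[i, j] = exp(-2 * alpha * (T - t_ij)) * (1 - exp(-2 * alpha * t_ij)) /
#' (2 * alpha)`. As alpha tends to 0 this converges entrywise to the
#' Brownian-motion covariance.
#'
#' @param tree ultrametric [ape::phylo].
#' @param alpha selection strength, > 0.
#' @return symmetric matrix (tips x tips), per unit sigma^2.
#' @export
ou_covariance <- function(tree, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a single positive number", call. = FALSE)
  }
  validate_phylogeny(tree, require_ultrametric = TRUE)
  tshared <- ape::vcv(tree)
  T_depth <- max(diag(tshared))
  exp(-2 * alpha * (T_depth - tshared)) *
    (1 - exp(-2 * alpha * tshared)) / (2 * alpha)
}

# Gaussian GLS machinery: profile beta and sigma2 out of the likelihood.
# Returns everything needed to assemble a fit at a given V.
.gls_profile <- function(y, X, V) {
  n <- length(y)
  L <- tryCatch(chol(V), error = function(e) {
    stop("covariance matrix is not positive definite", call. = FALSE)
  })
  # whiten: solve L' z = x  =>  z = (L')^-1 x, with V = L'L (R's chol is upper)
  wy <- backsolve(L, y, transpose = TRUE)
  wX <- backsolve(L, X, transpose = TRUE)
  XtX <- crossprod(wX)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X)) stop("singular design matrix", call. = FALSE)
  beta <- solve(qrX, crossprod(wX, wy))
  r <- wy - wX %*% beta
  rss <- sum(r^2)
  sigma2_ml <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  # GLS intercept-only fit for the total sum of squares
  w1 <- backsolve(L, rep(1, n), transpose = TRUE)
  mu <- sum(w1 * wy) / sum(w1^2)
  tss <- sum((wy - w1 * mu)^2)
  list(beta = drop(beta), rss = rss, tss = tss, sigma2_ml = sigma2_ml,
       loglik = loglik, XtVinvX = XtX, n = n, p = ncol(X))
}

.assemble_fit <- function(prof, model, alpha, response, colnames_X) {
  n <- prof$n
  p <- prof$p
  sigma2_err <- prof$rss / (n - p)
  vc <- sigma2_err * solve(prof$XtVinvX)
  se <- sqrt(diag(vc))
  tval <- prof$beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  k <- p + 1L + as.integer(model == "OU")  # + sigma2 (+ alpha for OU)
  r2 <- 1 - prof$rss / prof$tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  coef_tab <- data.frame(term = colnames_X, estimate = unname(prof$beta),
                         se = unname(se), t = unname(tval),
                         p_value = unname(pval), row.names = NULL)
  structure(list(model = model, response = response,
                 coefficients = coef_tab,
                 sigma2 = prof$sigma2_ml, alpha = alpha,
                 loglik = prof$loglik, k = k,
                 AIC = 2 * k - 2 * prof$loglik,
                 adj_r2 = adj_r2, n = n),
            class = "phylo_lm")
}

#' Phylogenetic linear regression by maximum likelihood
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * V(theta))`, where V is the
#' Brownian-motion covariance of the tree or the fixed-root
#' Ornstein-Uhlenbeck covariance with selection strength alpha. beta and
#' sigma2 are profiled out in closed form (GLS and ML variance); for OU,
#' alpha is optimized numerically on the log scale over
#' `[1e-8, 50 / depth]` with three interval restarts, since the profile
#' likelihood is nearly flat close to the BM boundary. Standard errors use
#' the residual-degree-of-freedom variance estimate `RSS / (n - p)` and
#' p-values come from two-sided t tests with `n - p` degrees of freedom.
#' AIC counts the coefficients, sigma2 and (for OU) alpha as free
#' parameters.
#'
#' @param y named numeric response vector (names = species).
#' @param X design matrix with rownames matching `y` (e.g. from
#'   [design_matrix()]).
#' @param tree [ape::phylo] covering the species; extra tips are dropped.
#' @param model `"BM"` or `"OU"`.
#' @param response label stored in the fit (for reporting).
#' @param alpha optional fixed alpha (skips optimization; OU only).
#' @return object of class `phylo_lm`: coefficient table (estimate, se, t,
#'   p_value), `sigma2` (ML), `alpha` (OU), `loglik`, `AIC`, `adj_r2`, `n`.
#' @export
phylo_lm <- function(y, X, tree, model = c("BM", "OU"),
                     response = deparse(substitute(y)), alpha = NULL) {
  model <- match.arg(model)
  force(response)
  if (is.null(names(y)) || is.null(rownames(X))) {
    stop("y and X must carry species names", call. = FALSE)
  }
  common <- intersect(intersect(names(y), rownames(X)), tree$tip.label)
  if (length(common) < ncol(X) + 1L) {
    stop("too few species shared between traits and tree", call. = FALSE)
  }
  dropped <- length(tree$tip.label) - length(common)
  if (dropped > 0) {
    tree <- ape::keep.tip(tree, common)
  }
  ord <- tree$tip.label
  y <- y[ord]
  X <- X[ord, , drop = FALSE]
  if (anyNA(y) || anyNA(X)) stop("missing trait values", call. = FALSE)

  if (model == "BM") {
    prof <- .gls_profile(y, X, bm_covariance(tree))
    return(.assemble_fit(prof, "BM", NA_real_, response, colnames(X)))
  }
  validate_phylogeny(tree, require_ultrametric = TRUE)
  tshared <- ape::vcv(tree)
  T_depth <- max(diag(tshared))
  ou_v <- function(a) {
    exp(-2 * a * (T_depth - tshared)) * (1 - exp(-2 * a * tshared)) / (2 * a)
  }
  if (!is.null(alpha)) {
    prof <- .gls_profile(y, X, ou_v(alpha))
    return(.assemble_fit(prof, "OU", alpha, response, colnames(X)))
  }
  lo <- log(1e-8)
  hi <- log(50 / T_depth)
  nll <- function(la) -.gls_profile(y, X, ou_v(exp(la)))$loglik
  cuts <- seq(lo, hi, length.out = 4L)
  best <- NULL
  for (i in seq_len(3L)) {
    o <- stats::optimize(nll, lower = cuts[i], upper = cuts[i + 1L],
                         tol = 1e-8)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (!is.finite(best$objective)) {
    stop("OU likelihood optimization failed to converge (alpha search in [",
         signif(exp(lo), 3), ", ", signif(exp(hi), 3), "])", call. = FALSE)
  }
  a_hat <- exp(best$minimum)
  prof <- .gls_profile(y, X, ou_v(a_hat))
  .assemble_fit(prof, "OU", a_hat, response, colnames(X))
}

#' @export
print.phylo_lm <- function(x, ...) {
  cat("Phylogenetic regression (", x$model, "), response: ", x$response,
      ", n = ", x$n, "\n", sep = "")
  print(x$coefficients, digits = 5)
  cat("sigma2 =", format(x$sigma2, digits = 5))
  if (x$model == "OU") cat(", alpha =", format(x$alpha, digits = 5))
  cat(", logLik =", format(x$loglik, digits = 6),
      ", AIC =", format(x$AIC, digits = 6),
      ", adj R2 =", format(x$adj_r2, digits = 4), "\n")
  invisible(x)
}

#' Fit one response under the standard temperature-class + GC design
#'
#' Convenience wrapper: builds the design matrix from metadata, joins the
#' response by species name and calls [phylo_lm()].
#'
#' @param response column name in `traits`.
#' @param traits data.frame with `species`, `gc`, `temp_class` and the
#'   response column.
#' @param tree [ape::phylo].
#' @param model `"BM"` or `"OU"`.
#' @return a `phylo_lm` fit.
#' @export
fit_phylo_lm <- function(response, traits, tree, model = c("BM", "OU")) {
  model <- match.arg(model)
  if (!response %in% names(traits)) {
    stop("response '", response, "' not in trait table", call. = FALSE)
  }
  X <- design_matrix(traits)
  # a temperature class absent from the data leaves an all-zero indicator;
  # drop it (the coefficient is not estimable) rather than fail
  const_col <- apply(X, 2, function(v) length(unique(v)) == 1L)
  const_col["intercept"] <- FALSE
  if (any(const_col)) {
    message("dropping term(s) with no variation: ",
            paste(colnames(X)[const_col], collapse = ", "))
    X <- X[, !const_col, drop = FALSE]
  }
  y <- traits[[response]]
  names(y) <- traits$species
  phylo_lm(y, X, tree, model = model, response = response)
}

#' Select among fitted covariance models by AIC
#'
#' The minimum-AIC fit wins; when the AIC difference is below 2 units the
#' fit with the fewest free parameters is preferred, and exact ties go to
#' the earlier fit in the input order.
#'
#' @param fits list of `phylo_lm` fits of the same regression.
#' @return the chosen fit, with `delta_AIC` (AIC of the alternative minus
#'   AIC of the chosen fit, when two or more fits are supplied) attached.
#' @export
select_model <- function(fits) {
  if (!length(fits)) stop("no fits supplied", call. = FALSE)
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  kpar <- vapply(fits, `[[`, numeric(1), "k")
  best_aic <- min(aic)
  cand <- which(aic - best_aic < 2)
  pick <- cand[order(kpar[cand], aic[cand], cand)][1L]
  chosen <- fits[[pick]]
  chosen$delta_AIC <- if (length(fits) > 1L) {
    unname(min(aic[-pick]) - aic[pick])
  } else NA_real_
  chosen
}

# Phylogenetic independent contrasts ----------------------------------------

#' Phylogenetic independent contrasts
#'
#' Standardized trait contrasts at internal nodes (Felsenstein's pruning
#' algorithm, via [ape::pic()]). Polytomies are resolved to zero-length
#' branches with a warning; zero-length terminal branch pairs would make a
#' contrast's variance zero, so branch lengths are as supplied.
#'
#' @param tree [ape::phylo].
#' @param trait named numeric vector over the tips.
#' @return numeric vector of n - 1 contrasts, named by internal node.
#' @export
pic_contrasts <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait must be named by species",
                                  call. = FALSE)
  if (!setequal(names(trait), tree$tip.label)) {
    stop("trait names do not match tree tips", call. = FALSE)
  }
  if (!ape::is.binary(tree)) {
    warning("resolving polytomies to zero-length branches", call. = FALSE)
    tree <- ape::multi2di(tree)
  }
  ape::pic(trait[tree$tip.label], tree)
}

#' Spearman correlation between two contrast sets
#'
#' Rank correlation of two vectors of phylogenetic independent contrasts
#' (same tree, same node order) with the asymptotic two-sided p-value;
#' ties receive average ranks.
#'
#' @param c1,c2 contrast vectors of equal length.
#' @return list with `rho` and `p_value`.
#' @export
spearman_pic <- function(c1, c2) {
  if (length(c1) != length(c2)) stop("contrast vectors differ in length",
                                     call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(c1, c2, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
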