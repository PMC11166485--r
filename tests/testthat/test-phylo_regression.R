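test_that("design matrix uses mesophile as the reference class", {
  md <- data.frame(species = c("a", "b", "c"),
                   gc = c(0.50, 0.60, 0.40),
                   temp_class = c("mesophile", "thermophile",
                                  "psychrophile"))
  X <- design_matrix(md)
  expect_equal(colnames(X), c("intercept", "xPsychro", "xThermo", "gc"))
  expect_equal(unname(X["a", ]), c(1, 0, 0, 0.50))
  expect_equal(unname(X["b", ]), c(1, 0, 1, 0.60))
  expect_equal(unname(X["c", ]), c(1, 1, 0, 0.40))
  md$temp_class[1] <- "lukewarmophile"
  expect_error(design_matrix(md), "unknown temp_class")
})

test_that("BM covariance is the shared root-to-ancestor path length", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- bm_covariance(tr)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(unname(diag(V)[c("A", "B", "C")]), c(2, 2, 2))
  star <- ape::read.tree(text = "(A:3,B:3,C:3);")
  expect_equal(unname(bm_covariance(star)), 3 * diag(3))
  neg <- ape::read.tree(text = "((A:1,B:-1):1,C:2);")
  expect_error(bm_covariance(neg), "negative")
})

test_that("OU covariance matches the fixed-root formula and its limits", {
  tr <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1);")
  a <- 1
  V <- ou_covariance(tr, a)
  T_depth <- 1
  # diagonal: shared time T
  expect_equal(unname(diag(V)), rep((1 - exp(-2 * a)) / (2 * a), 3))
  # off-diagonal at shared time 0.5, evaluated independently
  expect_equal(V["A", "B"],
               exp(-2 * 1 * 0.5) * (1 - exp(-2 * 1 * 0.5)) / 2,
               tolerance = 1e-12)
  # alpha -> 0 converges entrywise to BM
  expect_equal(unname(ou_covariance(tr, 1e-9)), unname(bm_covariance(tr)),
               tolerance = 1e-6)
  expect_error(ou_covariance(tr, 0), "positive")
  nonultra <- ape::read.tree(text = "((A:1,B:1):1,C:5);")
  expect_error(ou_covariance(nonultra, 1), "ultrametric")
})

test_that("BM regression on a star tree equals ordinary least squares", {
  set.seed(21)
  n <- 30
  star <- ape::stree(n, type = "star")
  star$edge.length <- rep(1, n)
  md <- data.frame(species = star$tip.label,
                   gc = runif(n, 0.3, 0.7),
                   temp_class = sample(c("mesophile", "thermophile",
                                         "psychrophile"), n, replace = TRUE))
  y <- 2 + 5 * md$gc + rnorm(n)
  names(y) <- md$species
  X <- design_matrix(md)
  fit <- phylo_lm(y, X, star, model = "BM")
  ols <- lm(y ~ 0 + X)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ols)))), tolerance = 1e-8)
  expect_equal(fit$coefficients$p_value,
               unname(summary(ols)$coefficients[, 4]), tolerance = 1e-8)
})

test_that("noise-free data are fit perfectly", {
  d <- make_regression_data(n = 25, seed = 5)
  y0 <- drop(d$X %*% c(2, 0.5))
  names(y0) <- rownames(d$X)
  fit <- phylo_lm(y0, d$X, d$tree, model = "BM")
  expect_equal(fit$coefficients$estimate, c(2, 0.5), tolerance = 1e-8)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-6)
})

test_that("BM ML estimates agree with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  d <- make_regression_data(n = 40, seed = 8)
  fit <- phylo_lm(d$y, d$X, d$tree, model = "BM")
  df <- data.frame(y = d$y, x = d$x, species = names(d$y))
  g <- nlme::gls(y ~ x, data = df,
                 correlation = ape::corBrownian(1, d$tree, form = ~species),
                 method = "ML")
  expect_equal(fit$coefficients$estimate, unname(coef(g)),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
})

test_that("the OU fit recovers strong selection and nests BM", {
  d <- make_regression_data(n = 80, seed = 13, sigma2 = 2, model = "OU",
                            alpha = 5)
  fit_ou <- phylo_lm(d$y, d$X, d$tree, model = "OU")
  fit_bm <- phylo_lm(d$y, d$X, d$tree, model = "BM")
  expect_gt(fit_ou$alpha, 0)
  expect_gte(fit_ou$loglik, fit_bm$loglik - 1e-6)  # OU nests BM (alpha -> 0)
  expect_equal(fit_ou$k, fit_bm$k + 1)
  # likelihood at huge alpha approaches the independent-observations
  # (diagonal-covariance) likelihood, i.e. the iid ML of ordinary lm
  fit_big <- phylo_lm(d$y, d$X, d$tree, model = "OU", alpha = 1e6)
  ll_iid <- as.numeric(stats::logLik(lm(d$y ~ d$x)))
  expect_equal(fit_big$loglik, ll_iid, tolerance = 1e-4)
})

test_that("likelihood is invariant to species and column order", {
  d <- make_regression_data(n = 30, seed = 17)
  fit <- phylo_lm(d$y, d$X, d$tree, model = "BM")
  perm <- sample(names(d$y))
  fit_perm <- phylo_lm(d$y[perm], d$X[perm, ], d$tree, model = "BM")
  expect_equal(fit$loglik, fit_perm$loglik, tolerance = 1e-10)
  Xsw <- d$X[, c(2, 1)]
  fit_sw <- phylo_lm(d$y, Xsw, d$tree, model = "BM")
  expect_equal(fit$AIC, fit_sw$AIC, tolerance = 1e-10)
  # singular designs are rejected
  Xs <- cbind(d$X, dup = d$X[, 2])
  expect_error(phylo_lm(d$y, Xs, d$tree, model = "BM"), "singular")
})

test_that("model selection follows minimum AIC with a parsimony guard", {
  f <- function(aic, k) structure(list(AIC = aic, k = k, model = "x"),
                                  class = "phylo_lm")
  expect_equal(select_model(list(f(100, 5), f(104, 6)))$AIC, 100)
  expect_equal(select_model(list(f(100, 6), f(101, 5)))$AIC, 101)
  expect_equal(select_model(list(f(100, 5), f(100, 5)))$AIC, 100)
  first <- f(100, 5); first$tag <- "first"
  second <- f(100, 5); second$tag <- "second"
  expect_equal(select_model(list(first, second))$tag, "first")
  expect_equal(select_model(list(f(107, 6), f(100, 5)))$delta_AIC, 7)
  expect_error(select_model(list()), "no fits")
})

test_that("contrasts match closed forms and a brute-force GLS identity", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(pic_contrasts(cherry, c(A = 3, B = 1))), sqrt(2))
  d <- make_regression_data(n = 16, seed = 23)
  const <- setNames(rep(4, 16), d$tree$tip.label)
  expect_true(all(pic_contrasts(d$tree, const) == 0))
  # PIC through-origin slope equals the BM GLS slope (single covariate)
  cy <- pic_contrasts(d$tree, d$y)
  cx <- pic_contrasts(d$tree, d$x)
  slope_pic <- sum(cx * cy) / sum(cx^2)
  fit <- phylo_lm(d$y, d$X, d$tree, model = "BM")
  expect_equal(slope_pic, fit$coefficients$estimate[2], tolerance = 1e-6)
  expect_error(pic_contrasts(d$tree, c(bad = 1)), "match")
})

test_that("Spearman correlation of contrasts behaves as a rank statistic", {
  set.seed(31)
  c1 <- rnorm(20)
  expect_equal(spearman_pic(c1, c1)$rho, 1)
  expect_equal(spearman_pic(c1, -c1)$rho, -1)
  # brute-force rank computation on a small fixed vector
  a <- c(0.3, -1.2, 0.8, 0.1, -0.5)
  b <- c(1.0, 0.2, -0.3, 0.9, 0.4)
  rho_hand <- cor(rank(a), rank(b))
  expect_equal(spearman_pic(a, b)$rho, rho_hand, tolerance = 1e-12)
  expect_error(spearman_pic(a, b[1:3]), "length")
})
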